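# Digital phantoms: a geometric short-axis cardiac layout and a 36-vial
# property-sweep phantom. Tissue (T1, T2) values are placed on the dictionary
# grid where applicable; T2* and PDFF are continuous-valued.

new_phantom <- function(label, properties, fov_mm) {
  stopifnot(all(unique(label[label > 0]) %in% properties$label))
  stopifnot(all(properties$pdff >= 0 & properties$pdff <= 1))
  structure(list(label = label, properties = properties,
                 matrix = nrow(label), fov_mm = fov_mm),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital phantom %dx%d, %d tissue classes\n", x$matrix, x$matrix,
              nrow(x$properties)))
  print(x$properties, row.names = FALSE)
  invisible(x)
}

ellipse_mask <- function(n, cx, cy, rx, ry) {
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  outer(xs, xs, function(x, y) ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1)
}

#' Geometric short-axis cardiac phantom
#'
#' A stylized mid-ventricular short-axis slice: left-ventricular blood pool,
#' myocardial ring, right ventricle, liver, subcutaneous fat layer and a body
#' (muscle) background. Healthy myocardium carries T1 = 950 ms, T2 = 48 ms,
#' T2* = 30 ms, PDFF = 1%; each pathological case replaces one myocardial
#' property with its pathological value (T1 1250 ms, T2 65 ms, T2* 15 ms, or
#' PDFF 10%). The fat component of every mixed voxel has T1 = 250 ms,
#' T2 = 60 ms, T2* = 20 ms.
#'
#' @param matrix Matrix size (>= 32).
#' @param case One of `"healthy"`, `"pathT1"`, `"pathT2"`, `"pathT2star"`,
#'   `"pathPDFF"`.
#' @param fov_mm Field of view (default 300).
#' @return A `digital_phantom`.
#' @export
make_cardiac_phantom <- function(matrix = 96,
                                 case = c("healthy", "pathT1", "pathT2",
                                          "pathT2star", "pathPDFF"),
                                 fov_mm = 300) {
  case <- match.arg(case)
  if (matrix < 32) stop("matrix must be at least 32", call. = FALSE)
  n <- as.integer(matrix)
  lab <- matrix(0L, n, n)
  body <- ellipse_mask(n, 0, 0, 0.42, 0.36)
  fatring <- body & !ellipse_mask(n, 0, 0, 0.385, 0.325)
  lv <- ellipse_mask(n, -0.05, 0.10, 0.085, 0.085)
  myo <- ellipse_mask(n, -0.05, 0.10, 0.145, 0.145) & !lv
  rv <- ellipse_mask(n, -0.07, -0.12, 0.14, 0.09) &
    !ellipse_mask(n, -0.05, 0.10, 0.16, 0.16)
  liver <- ellipse_mask(n, 0.22, -0.05, 0.13, 0.20)
  lab[body] <- 1L
  lab[fatring] <- 5L
  lab[liver] <- 4L
  lab[rv] <- 3L
  lab[myo] <- 2L
  lab[lv] <- 6L
  myo_vals <- list(t1 = 950, t2 = 48, t2star = 30, pdff = 0.01)
  if (case == "pathT1") myo_vals$t1 <- 1250
  if (case == "pathT2") myo_vals$t2 <- 65
  if (case == "pathT2star") myo_vals$t2star <- 15
  if (case == "pathPDFF") myo_vals$pdff <- 0.10
  props <- data.frame(
    label = 1:6,
    tissue = c("body", "myocardium", "rv_blood", "liver", "subcut_fat",
               "lv_blood"),
    t1_ms = c(1000, myo_vals$t1, 1550, 570, 1000, 1550),
    t2_ms = c(44, myo_vals$t2, 240, 46, 40, 240),
    t2star_ms = c(30, myo_vals$t2star, 60, 28, 30, 60),
    pdff = c(0, myo_vals$pdff, 0, 0.03, 0.90, 0),
    m0 = c(0.8, 1, 1, 0.9, 1, 1),
    fat_t1_ms = 250, fat_t2_ms = 60, fat_t2star_ms = 20)
  new_phantom(lab, props, fov_mm)
}

#' 36-vial property-sweep phantom
#'
#' Thirty-six disks on a 6x6 grid carrying the full factorial of
#' T1 = (300, 800, 1200) ms, T2 = (30, 70, 150) ms, T2* = (15, 30) ms and
#' PDFF = (5%, 15%); the fat component is fixed at T1 = 250, T2 = 60,
#' T2* = 20 ms. Used for confounder (off-target correlation) analysis.
#'
#' @param matrix Matrix size (>= 64).
#' @param fov_mm Field of view (default 300).
#' @return A `digital_phantom`.
#' @export
make_vial_phantom <- function(matrix = 96, fov_mm = 300) {
  if (matrix < 64) stop("matrix must be at least 64", call. = FALSE)
  n <- as.integer(matrix)
  lab <- matrix(0L, n, n)
  grid <- expand.grid(t1_ms = c(300, 800, 1200), t2_ms = c(30, 70, 150),
                      t2star_ms = c(15, 30), pdff = c(0.05, 0.15))
  centers <- expand.grid(i = seq_len(6), j = seq_len(6))
  r <- 0.055
  for (v in seq_len(36)) {
    cx <- (centers$i[v] - 3.5) / 7.2
    cy <- (centers$j[v] - 3.5) / 7.2
    lab[ellipse_mask(n, cx, cy, r, r)] <- v
  }
  props <- data.frame(label = seq_len(36),
                      tissue = sprintf("vial%02d", seq_len(36)),
                      t1_ms = grid$t1_ms, t2_ms = grid$t2_ms,
                      t2star_ms = grid$t2star_ms, pdff = grid$pdff,
                      m0 = 1, fat_t1_ms = 250, fat_t2_ms = 60,
                      fat_t2star_ms = 20)
  new_phantom(lab, props, fov_mm)
}

#' Property maps of a phantom
#'
#' Expands the per-label property table into per-voxel truth maps.
#' @param phantom A `digital_phantom`.
#' @return Named list of matrices (`t1_ms`, `t2_ms`, `t2star_ms`, `pdff`,
#'   `m0`).
#' @export
phantom_truth_maps <- function(phantom) {
  n <- phantom$matrix
  out <- list()
  for (f in c("t1_ms", "t2_ms", "t2star_ms", "pdff", "m0")) {
    m <- matrix(0, n, n)
    for (r in seq_len(nrow(phantom$properties))) {
      m[phantom$label == phantom$properties$label[r]] <- phantom$properties[[f]][r]
    }
    out[[f]] <- m
  }
  out
}
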