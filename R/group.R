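#' Group-mean source coordinates
#'
#' Arithmetic mean and standard error of the mean, per axis, of peak
#' source coordinates grouped by finger and condition.
#'
#' @param coords data.frame with columns `subject`, `finger`,
#'   `condition`, `x`, `y`, `z` (one row per subject x finger x
#'   condition).
#' @return data.frame with one row per finger x condition cell: mean and
#'   SEM of each axis and the subject count `n`.
#' @export
mean_coordinates <- function(coords) {
  need <- c("subject", "finger", "condition", "x", "y", "z")
  if (!all(need %in% names(coords)))
    stop_ckc("coords must have columns %s", paste(need, collapse = ", "))
  key <- interaction(coords$finger, coords$condition, drop = TRUE)
  if (anyDuplicated(paste(coords$subject, key)))
    stop_ckc("duplicate (subject, finger, condition) rows")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    d <- coords[key == k, ]
    if (nrow(d) < 2)
      stop_ckc("cell %s has fewer than 2 subjects", k)
    m <- colMeans(d[, c("x", "y", "z")])
    s <- apply(d[, c("x", "y", "z")], 2, stats::sd) / sqrt(nrow(d))
    data.frame(finger = d$finger[1], condition = d$condition[1],
               x = m[1], y = m[2], z = m[3],
               sem_x = s[1], sem_y = s[2], sem_z = s[3], n = nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Euclidean distance between two mean coordinates
#'
#' @param a,b length-3 numeric coordinates (mm).
#' @return distance in mm.
#' @export
pairwise_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || !all(is.finite(c(a, b))))
    stop_ckc("coordinates must be finite length-3 vectors")
  sqrt(sum((a - b)^2))
}

#' Permutation test on the distance between group-mean coordinates
#'
#' Tests whether two sets of subject-paired 3-D peak-source coordinates
#' (e.g., two fingers, or two conditions) differ in location. The
#' observed statistic is the Euclidean distance between the two group
#' means. The null distribution permutes the coordinates between the two
#' labels: by default each subject's pair is swapped independently with
#' probability 1/2 (respecting the repeated-measures pairing); pooled
#' relabeling is available via `method = "pooled"`. With
#' `exact = TRUE` all `2^n` paired swap patterns are enumerated instead
#' of sampled. The p value uses the add-one rule
#' `(#{null >= observed} + 1) / (n_perm + 1)` (exact mode:
#' `#{null >= observed} / 2^n`).
#'
#' @param coords_a,coords_b n x 3 matrices of subject coordinates, rows
#'   paired by subject.
#' @param n_perm number of permutations (ignored when `exact = TRUE`).
#' @param seed RNG seed for reproducibility.
#' @param method `"paired"` (default, per-subject swaps) or `"pooled"`
#'   (relabel the pooled 2n observations).
#' @param exact enumerate all paired swap patterns (paired method only).
#' @return object of class `ckc_perm`: `observed` (mm), `p_value`,
#'   `null_samples`, `seed`, `method`.
#' @export
permutation_distance_test <- function(coords_a, coords_b, n_perm = 100000,
                                      seed = NULL,
                                      method = c("paired", "pooled"),
                                      exact = FALSE) {
  method <- match.arg(method)
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!identical(dim(A), dim(B)) || ncol(A) != 3L)
    stop_ckc("coordinate sets must be subject-paired n x 3 matrices of equal size")
  n <- nrow(A)
  if (!exact && !is_count(n_perm)) stop_ckc("n_perm must be a positive integer")
  observed <- pairwise_distance(colMeans(A), colMeans(B))
  D <- A - B                                 # per-subject difference vectors
  if (exact) {
    if (method != "paired") stop_ckc("exact enumeration applies to the paired method")
    if (n > 20) stop_ckc("exact enumeration is limited to n <= 20 subjects")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- sqrt(rowSums((signs %*% D / n)^2))
    p <- sum(null >= observed - 1e-12) / nrow(signs)
    m <- nrow(signs)
  } else {
    set_seed_if(seed)
    if (method == "paired") {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
      null <- sqrt(rowSums((signs %*% D / n)^2))
    } else {
      pool <- rbind(A, B)
      null <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(2 * n, n)
        pairwise_distance(colMeans(pool[idx, , drop = FALSE]),
                          colMeans(pool[-idx, , drop = FALSE]))
      }, numeric(1))
    }
    p <- (sum(null >= observed - 1e-12) + 1) / (n_perm + 1)
    m <- n_perm
  }
  structure(list(observed = observed, p_value = p, null_samples = m,
                 seed = seed, method = method, exact = exact, n = n),
            class = "ckc_perm")
}

#' @export
print.ckc_perm <- function(x, ...) {
  cat("Permutation test on group-mean coordinate distance\n")
  cat(sprintf("  n = %d subjects, %s%s, %d null samples\n", x$n, x$method,
              if (x$exact) " (exact enumeration)" else "", x$null_samples))
  cat(sprintf("  observed distance = %.2f mm, p = %.4g\n", x$observed, x$p_value))
  invisible(x)
}

#' Tidy condition-contrast table of CKC strengths
#'
#' Assembles per-cell peak CKC values into the long-format table consumed
#' by external repeated-measures ANOVA tooling: one row per subject x
#' finger x condition x level, deterministically ordered. Duplicate cells
#' are an error; cells listed in `expect` but absent are flagged with
#' `missing = TRUE` rather than dropped.
#'
#' @param results data.frame with columns `subject`, `finger`,
#'   `condition`, `ckc` and optionally `level` (`"sensor"` or
#'   `"source"`, default `"sensor"`).
#' @param expect optional data.frame of cells (`subject`, `finger`,
#'   `condition`, `level`) that must be present.
#' @return ordered data.frame with a logical `missing` column.
#' @export
condition_contrast_table <- function(results, expect = NULL) {
  need <- c("subject", "finger", "condition", "ckc")
  if (!all(need %in% names(results)))
    stop_ckc("results must have columns %s", paste(need, collapse = ", "))
  if (is.null(results$level)) results$level <- "sensor"
  key <- paste(results$subject, results$finger, results$condition, results$level)
  if (anyDuplicated(key))
    stop_ckc("duplicate cell(s): %s", paste(unique(key[duplicated(key)]), collapse = "; "))
  results$missing <- FALSE
  if (!is.null(expect)) {
    ekey <- paste(expect$subject, expect$finger, expect$condition,
                  expect$level %||% "sensor")
    absent <- setdiff(ekey, key)
    if (length(absent)) {
      parts <- do.call(rbind, strsplit(absent, " "))
      add <- data.frame(subject = parts[, 1], finger = parts[, 2],
                        condition = parts[, 3], ckc = NA_real_,
                        level = parts[, 4], missing = TRUE)
      results <- rbind(results[, names(add)], add)
    }
  }
  o <- order(results$level, results$condition, results$finger, results$subject)
  out <- results[o, c("subject", "finger", "condition", "level", "ckc", "missing")]
  rownames(out) <- NULL
  out
}
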