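# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify: every prefix sum,
# covariance and confusion tally is recomputed by explicit loops.

# maximal prefix length whose mass is <= each k*F% threshold, testing
# every prefix length 0..L directly
oracle_boundaries <- function(column, F) {
  L <- length(column)
  total <- sum(column)
  n_seg <- 50 / F
  scan <- function(x) {
    if (total == 0) return(rep(0L, n_seg))
    sapply(seq_len(n_seg), function(k) {
      thr <- (k * F / 100) * total
      best <- 0L
      for (i in 0:L) {
        if (sum(x[seq_len(i)]) <= thr) best <- i
      }
      best
    })
  }
  list(top = scan(column), bottom = scan(rev(column)))
}

# direct summation form of the lagged auto covariance
oracle_auto_covariance <- function(x, mu, g) {
  n <- length(x)
  if (n <= g) return(0)
  acc <- 0
  for (i in seq_len(n - g)) {
    acc <- acc + (x[i] - mu) * (x[i + g] - mu)
  }
  acc / (n - g)
}

# expand a confusion matrix to a per-sample (true, predicted) list and
# recount one-vs-rest tallies per class
oracle_metrics <- function(conf) {
  classes <- rownames(conf)
  true <- character(0)
  pred <- character(0)
  for (i in seq_len(nrow(conf))) {
    for (j in seq_len(ncol(conf))) {
      true <- c(true, rep(classes[i], conf[i, j]))
      pred <- c(pred, rep(classes[j], conf[i, j]))
    }
  }
  out <- lapply(classes, function(cl) {
    TP <- sum(true == cl & pred == cl)
    FN <- sum(true == cl & pred != cl)
    FP <- sum(true != cl & pred == cl)
    TN <- sum(true != cl & pred != cl)
    den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    list(sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
         specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
         mcc = if (den2 == 0) 0 else (TP * TN - FP * FN) / sqrt(den2))
  })
  names(out) <- classes
  list(per_class = out, overall = 100 * sum(true == pred) / length(true))
}

# small random normalized-profile pair for pipeline tests
random_profile_pair <- function(L, id = "p") {
  raw <- matrix(sample(-8:12, L * 20, replace = TRUE), L, 20)
  seq <- paste(sample(segstruct::aa_alphabet(), L, replace = TRUE),
               collapse = "")
  evo <- segstruct::normalize_profile(
    segstruct::evolutionary_profile(id, seq, raw))
  sm <- matrix(stats::runif(L * 3), L, 3)
  sm <- sm / rowSums(sm)
  struct <- segstruct::structural_profile(id, sm)
  list(evo = evo, struct = struct)
}

# a linearly separable two-blob feature table for SVM sanity checks
separable_blobs <- function(n_per_class = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * 2, mean = 0, sd = 0.1), ncol = 2),
               matrix(rnorm(n_per_class * 2, mean = 5, sd = 0.1), ncol = 2))
  })
  tibble::tibble(
    protein_id = sprintf("s%02d", seq_len(2 * n_per_class)),
    class = rep(c("all-alpha", "all-beta"), each = n_per_class),
    f1 = x[, 1], f2 = x[, 2])
}
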