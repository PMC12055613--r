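#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of the average-ranked data
#' (ties receive midranks), the preferred association measure for small
#' clinical samples. The two-sided p-value is computed by exact permutation
#' when `n <= exact_max`: every one of the n! orderings of `y` is
#' enumerated and the p-value is the proportion with |rho| at least the
#' observed |rho|. For larger n the standard t approximation with n - 2
#' degrees of freedom is used.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite, neither
#'   constant.
#' @param exact_max Largest n for which the permutation p-value is exact.
#' @return A list of class `reach_cor`: `method`, `estimate` (rho),
#'   `p_value` (two-sided, uncorrected), `n`, `exact` (whether the
#'   permutation path was used). Has [tidy()]/[glance()] methods.
#' @examples
#' cor_spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
cor_spearman <- function(x, y, exact_max = 8) {
  check_cor_input(x, y)
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    p <- t_pvalue(rho, n)
    exact <- FALSE
  }
  new_reach_cor("spearman", rho, p, n, exact)
}

#' Pearson product-moment correlation
#'
#' Standard linear correlation with the two-sided t-test p-value on n - 2
#' degrees of freedom; used for larger validation samples where the linear
#' association itself is of interest.
#'
#' @inheritParams cor_spearman
#' @return A list of class `reach_cor`; see [cor_spearman()].
#' @export
cor_pearson <- function(x, y) {
  check_cor_input(x, y)
  r <- cor(x, y)
  new_reach_cor("pearson", r, t_pvalue(r, length(x)), length(x), FALSE)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) {
    stop_reach("x and y must have equal length.",
               "reachstart_error_undefined_correlation")
  }
  if (length(x) < 3) {
    stop_reach("need at least 3 paired observations.",
               "reachstart_error_undefined_correlation")
  }
  check_number(x, "x", class = "reachstart_error_undefined_correlation")
  check_number(y, "y", class = "reachstart_error_undefined_correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_reach("correlation undefined for a constant vector.",
               "reachstart_error_undefined_correlation")
  }
}

t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# all n! permutations of 1..n as a matrix (rows); n is small by construction
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

new_reach_cor <- function(method, estimate, p, n, exact) {
  structure(list(method = method, estimate = unname(estimate),
                 p_value = unname(p), n = n, exact = exact),
            class = "reach_cor")
}

#' @export
print.reach_cor <- function(x, ...) {
  cat(sprintf("%s correlation: %s = %.4f, p = %.4g (n = %d%s)\n",
              if (x$method == "spearman") "Spearman" else "Pearson",
              if (x$method == "spearman") "rho" else "r",
              x$estimate, x$p_value, x$n,
              if (x$exact) ", exact permutation" else ""))
  invisible(x)
}

#' Benjamini-Hochberg significance flags at a fixed false discovery rate
#'
#' The step-up rule: sort the m uncorrected p-values ascending, find the
#' largest i with p(i) <= (i / m) * fdr, and reject hypotheses 1..i. Returns
#' reject/accept flags in the original order. No adjusted p-values are
#' produced — the procedure controls the FDR through flags, and uncorrected
#' p-values remain the quantity to report alongside them.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param fdr Target false discovery rate in (0, 1).
#' @return Logical vector of rejections, same order as `p`.
#' @examples
#' bh_adjust(c(0.004, 0.116, 0.126), fdr = 0.05)
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (length(p) == 0) return(logical(0))
  check_number(p, "p", 0, 1, class = "reachstart_error_invalid_spec")
  if (fdr <= 0 || fdr >= 1) {
    stop_reach("fdr must lie in (0, 1).", "reachstart_error_invalid_spec")
  }
  m <- length(p)
  ord <- order(p)
  below <- p[ord] <= seq_len(m) / m * fdr
  k <- if (any(below)) max(which(below)) else 0L
  flags <- logical(m)
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Spearman correlation battery of cohort measures against a target
#'
#' Correlates each named measure against the target measure (IoEE by
#' default) over complete cases, one Spearman test per measure, then applies
#' [bh_adjust()] once across the whole battery. The default battery is the
#' eleven clinical and reaction-time measures of the study design: MAS,
#' ARAT total and four subscores, normalized grip, the three per-condition
#' reaction times and the StartReact effect.
#'
#' @param cohort A cohort table (see [simulate_cohort()] /
#'   [read_cohort_csv()]).
#' @param target Column name of the target measure.
#' @param measures Named character vector: display label -> column name.
#' @param fdr False discovery rate for the battery-wide correction.
#' @return A tibble of class `correlation_table` with columns `measure`,
#'   `rho`, `p_uncorrected`, `n`, `significant_after_bh`.
#' @examples
#' correlation_table(simulate_cohort(cohort_spec(seed = 3)))
#' @export
correlation_table <- function(cohort, target = "ioee",
                              measures = default_battery(), fdr = 0.05) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(c(target, unname(measures)), names(cohort))
  if (length(missing_cols)) {
    stop_reach(paste0("unknown measure column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "reachstart_error_lookup")
  }
  rows <- purrr::imap_dfr(as.list(measures), function(col, label) {
    ok <- stats::complete.cases(cohort[[target]], cohort[[col]])
    if (sum(ok) < 3) {
      stop_reach(sprintf("fewer than 3 complete cases for `%s`.", col),
                 "reachstart_error_insufficient_data")
    }
    ct <- cor_spearman(cohort[[target]][ok], cohort[[col]][ok])
    tibble(measure = label, rho = ct$estimate,
           p_uncorrected = ct$p_value, n = ct$n)
  })
  rows$significant_after_bh <- bh_adjust(rows$p_uncorrected, fdr)
  structure(rows, class = c("correlation_table", class(tibble())),
            target = target, fdr = fdr)
}

#' @rdname correlation_table
#' @export
default_battery <- function() {
  c("Modified Ashworth Score (MAS)" = "mas",
    "Total ARAT score" = "arat_total",
    "ARAT grasp sub-score" = "arat_grasp",
    "ARAT grip sub-score" = "arat_grip",
    "ARAT pinch sub-score" = "arat_pinch",
    "ARAT gross sub-score" = "arat_gross",
    "Normalised hand grip (%)" = "grip_normalized",
    "Visual Reaction Time (VRT)" = "vrt_mean",
    "Visual-Auditory Reaction Time (VART)" = "vart_mean",
    "Visual-Startle Reaction Time (VSRT)" = "vsrt_mean",
    "StartReact (VART-VSRT)" = "startreact")
}

#' Normalize affected-side grip strength to the less-affected side
#'
#' Expresses the affected side's maximum grip force as a percentage of the
#' less-affected side's, removing between-subject strength differences.
#' Each input should already be the maximum over the repeated dynamometer
#' trials of that side.
#'
#' @param affected,less_affected Grip forces in kg; `less_affected` > 0.
#' @return Percentage (vectorised).
#' @examples
#' normalized_grip(7.5, 26.5)
#' @export
normalized_grip <- function(affected, less_affected) {
  check_number(affected, "affected", lower = 0,
               class = "reachstart_error_invalid_spec")
  check_number(less_affected, "less_affected",
               class = "reachstart_error_invalid_spec")
  if (any(less_affected <= 0)) {
    stop_reach("less_affected grip must be > 0 kg to normalize against.",
               "reachstart_error_division")
  }
  100 * affected / less_affected
}

#' Validate an ARAT score record
#'
#' Checks the four subscale scores against their published maxima — Grasp
#' 18, Grip 12, Pinch 18, Gross Movement 9 — and that the total (maximum
#' 57) equals their sum; the total is computed when absent.
#'
#' @param record A list or one-row data frame with `grasp`, `grip`,
#'   `pinch`, `gross` and optionally `total`.
#' @return The validated record as a one-row tibble including `total`.
#' @examples
#' validate_arat(list(grasp = 18, grip = 12, pinch = 18, gross = 9))
#' @export
validate_arat <- function(record) {
  record <- as.list(record)
  for (nm in names(arat_maxima)) {
    val <- record[[nm]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1 || is.na(val)) {
      stop_reach(sprintf("ARAT subscore `%s` is missing.", nm),
                 "reachstart_error_validation")
    }
    if (val < 0 || val > arat_maxima[[nm]]) {
      stop_reach(sprintf("ARAT subscore `%s` = %g outside [0, %d].",
                         nm, val, arat_maxima[[nm]]),
                 "reachstart_error_validation")
    }
  }
  total <- record$grasp + record$grip + record$pinch + record$gross
  if (!is.null(record$total) && !isTRUE(all.equal(record$total, total))) {
    stop_reach(sprintf("ARAT total %g does not equal subscore sum %g.",
                       record$total, total),
               "reachstart_error_validation")
  }
  tibble(grasp = record$grasp, grip = record$grip, pinch = record$pinch,
         gross = record$gross, total = total)
}
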