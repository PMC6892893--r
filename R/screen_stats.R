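#' Wilson score interval on a proportion
#'
#' Delegates to [stats::prop.test()] without continuity correction, which
#' is the Wilson score interval.
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @keywords internal
wilson_interval <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- suppressWarnings(
    stats::prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int)
  as.numeric(ci)
}

efficiency_result <- function(estimate, ci_low, ci_high, n) {
  tibble::tibble(estimate = estimate,
                 ci_low = max(0, min(ci_low, estimate)),
                 ci_high = min(100, max(ci_high, estimate)),
                 n = n)
}

#' Nuclease-mediated cell-killing (cutting) efficiency
#'
#' `(1 - a / b) * 100`, where `a` is the colony count with the on-targeting
#' gRNA plasmid and `b` the count with the non-targeting control. Active
#' cutting kills untransformed-repair cells, so fewer colonies under
#' targeting means higher efficiency. When `a > b` (more colonies under
#' targeting than control) the estimate is clamped to 0 with a warning.
#' A Wilson interval on the survival fraction `a / b` is propagated to the
#' efficiency scale.
#'
#' @param a Colony count, on-targeting gRNA.
#' @param b Colony count, non-targeting gRNA (> 0).
#' @param conf_level Confidence level for the Wilson interval.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high` (percent), `n`.
#' @export
cutting_efficiency <- function(a, b, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0)
  if (b == 0) stop("non-targeting colony count b must be positive")
  if (a > b) {
    warning("a > b: more colonies with targeting than control; clamping to 0%")
  }
  est <- max(0, min(100, (1 - a / b) * 100))
  ci <- wilson_interval(min(a, b), b, conf_level)
  efficiency_result(est, (1 - ci[2]) * 100, (1 - ci[1]) * 100, b)
}

#' Editing efficiency from a colorimetric screen
#'
#' White colonies carry the edited (inactivated) marker; red (galK on
#' MacConkey) or blue (lacZ) colonies are unedited. Efficiency is
#' `edited / (edited + unedited) * 100` with a Wilson interval.
#'
#' @param edited White (edited) colony count.
#' @param unedited Red or blue (unedited) colony count.
#' @param conf_level Confidence level for the Wilson interval.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high` (percent), `n`.
#' @export
editing_efficiency_color <- function(edited, unedited, conf_level = 0.95) {
  stopifnot(edited >= 0, unedited >= 0)
  n <- edited + unedited
  if (n == 0) stop("no colonies: edited + unedited must be positive")
  ci <- wilson_interval(edited, n, conf_level)
  efficiency_result(edited / n * 100, ci[1] * 100, ci[2] * 100, n)
}

#' Transformation efficiency in CFU per microgram
#'
#' @param cfu Colony-forming units counted on the plate.
#' @param micrograms Micrograms of plasmid transformed (> 0).
#' @param dilution_factor Fold-dilution applied before plating (default 1);
#'   the plate count is multiplied by this factor.
#' @return CFU per microgram (numeric scalar).
#' @export
transformation_efficiency <- function(cfu, micrograms, dilution_factor = 1) {
  stopifnot(cfu >= 0, dilution_factor > 0)
  if (micrograms <= 0) stop("micrograms must be positive")
  cfu * dilution_factor / micrograms
}

#' T7E1 indel rate from gel band intensities
#'
#' `100 * (1 - sqrt(1 - (b + c) / (a + b + c)))`, where `a` is the
#' integrated intensity of the undigested PCR product and `b`, `c` the
#' intensities of the two T7 endonuclease I cleavage products. The square
#' root converts the fraction of cleaved heteroduplex molecules into the
#' fraction of edited alleles under random re-annealing.
#'
#' @param a Undigested band intensity.
#' @param b,c Cleavage-product band intensities.
#' @return Indel percentage in `[0, 100]`.
#' @export
indel_rate <- function(a, b, c) {
  stopifnot(a >= 0, b >= 0, c >= 0)
  tot <- a + b + c
  if (tot == 0) stop("all band intensities are zero")
  100 * (1 - sqrt(1 - (b + c) / tot))
}

#' Apply a screen statistic to a table of counts
#'
#' Computes one efficiency result per input row; malformed rows are flagged
#' in the output (`ok = FALSE` with a `note`), never silently dropped.
#'
#' Expected columns by statistic: `"cutting"` needs `a`, `b`; `"color"`
#' needs `edited`, `unedited`; `"transform"` needs `cfu`, `micrograms`
#' (optional `dilution_factor`); `"indel"` needs `a`, `b`, `c`.
#'
#' @param counts Data frame of per-sample counts.
#' @param statistic One of `"cutting"`, `"color"`, `"transform"`, `"indel"`.
#' @param conf_level Confidence level for Wilson intervals where applicable.
#' @return Tibble: input columns plus `estimate`, `ci_low`, `ci_high`, `n`,
#'   `ok`, `note`.
#' @export
batch_table <- function(counts, statistic = c("cutting", "color",
                                              "transform", "indel"),
                        conf_level = 0.95) {
  statistic <- match.arg(statistic)
  counts <- tibble::as_tibble(counts)
  needed <- switch(statistic,
    cutting = c("a", "b"), color = c("edited", "unedited"),
    transform = c("cfu", "micrograms"), indel = c("a", "b", "c"))
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0L) {
    stop("input table lacks column(s): ", paste(missing, collapse = ", "))
  }
  one <- function(row) {
    tryCatch({
      res <- switch(statistic,
        cutting = cutting_efficiency(row$a, row$b, conf_level),
        color = editing_efficiency_color(row$edited, row$unedited, conf_level),
        transform = {
          dil <- if (!is.null(row$dilution_factor)) row$dilution_factor else 1
          tibble::tibble(estimate = transformation_efficiency(
            row$cfu, row$micrograms, dil),
            ci_low = NA_real_, ci_high = NA_real_, n = row$cfu)
        },
        indel = tibble::tibble(estimate = indel_rate(row$a, row$b, row$c),
                               ci_low = NA_real_, ci_high = NA_real_,
                               n = row$a + row$b + row$c))
      res$ok <- TRUE
      res$note <- NA_character_
      res
    }, error = function(e) {
      tibble::tibble(estimate = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, n = NA_real_, ok = FALSE,
                     note = conditionMessage(e))
    })
  }
  results <- lapply(seq_len(nrow(counts)), function(i) one(as.list(counts[i, ])))
  dplyr::bind_cols(counts, dplyr::bind_rows(results))
}
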