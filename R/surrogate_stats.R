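# Pseudo-dyad surrogate construction, real-vs-pseudo paired testing, and
# rank correlation of synchrony summaries with interaction-quality scores.

#' Sample a uniform derangement
#'
#' A derangement is a permutation with no fixed point. Sampling is by
#' rejection: uniform permutations are drawn until one has no fixed point,
#' which is uniform over derangements (acceptance probability approaches
#' 1/e, so rejection is cheap).
#'
#' @param n number of elements (at least 2).
#' @return An integer permutation of `1:n` with `sigma(i) != i` for all i.
#' @export
sample_derangement <- function(n) {
  if (n < 2L) stopf("a derangement needs at least 2 elements")
  repeat {
    sigma <- sample.int(n)
    if (!any(sigma == seq_len(n))) return(sigma)
  }
}

#' Build pseudo-dyads by re-pairing children with non-partner mothers
#'
#' Constructs one surrogate recording per real dyad by pairing child i with
#' mother sigma(i), where sigma is a uniformly sampled derangement -- so no
#' pseudo-pair coincides with a real pair and every mother is used exactly
#' once. Recordings are first truncated to the common minimum length
#' (coherence needs equal lengths; padding would fabricate data). With
#' `derangement = FALSE`, an unrestricted permutation conditioned only on
#' not being the identity is used instead.
#'
#' @param dyads list of [dyad_recording()] objects (at least 2).
#' @param seed integer seed; fixed seed gives a fixed pairing.
#' @param derangement require sigma(i) != i for all i (default TRUE).
#' @return List of pseudo [dyad_recording()]s with attribute `"pairing"`
#'   (the permutation sigma).
#' @export
make_pseudo_dyads <- function(dyads, seed = NULL, derangement = TRUE) {
  if (length(dyads) < 2L) stopf("need at least 2 dyads to build pseudo-dyads")
  n_min <- min(vapply(dyads, function(d) d$n_frames, integer(1)))
  dyads <- lapply(dyads, function(d) {
    if (d$n_frames > n_min) truncate_dyad(d, n_min) else d
  })
  sigma <- with_seed(seed, {
    if (derangement) {
      sample_derangement(length(dyads))
    } else {
      repeat {
        s <- sample.int(length(dyads))
        if (any(s != seq_along(dyads))) break
      }
      s
    }
  })
  pseudo <- lapply(seq_along(dyads), function(i) {
    dyad_recording(
      child = dyads[[i]]$child,
      mother = dyads[[sigma[i]]]$mother,
      dyad_id = sprintf("pseudo_%s_x_%s", dyads[[i]]$dyad_id,
                        dyads[[sigma[i]]]$dyad_id)
    )
  })
  attr(pseudo, "pairing") <- sigma
  pseudo
}

#' Paired t-test of real against pseudo-dyad synchrony
#'
#' Classical two-tailed paired-samples t-test on the per-dyad differences
#' (real minus pseudo). Degenerate inputs are handled explicitly: all-zero
#' differences give `t = 0, p = 1`; nonzero differences with zero variance
#' give an infinite t reported with `p = 0` and `degenerate = TRUE`.
#'
#' @param real,pseudo equal-length finite numeric vectors of per-dyad
#'   synchrony summaries, n >= 3.
#' @param pairing optional permutation used to build the pseudo-dyads,
#'   recorded in the result.
#' @param seed optional seed recorded in the result.
#' @return An object of class `surrogate_comparison`: `real_values`,
#'   `pseudo_values`, `t_stat`, `df`, `p_value`, `mean_diff`, `pairing`,
#'   `seed`, `degenerate`.
#' @export
paired_real_vs_pseudo <- function(real, pseudo, pairing = NULL, seed = NULL) {
  real <- as.numeric(real); pseudo <- as.numeric(pseudo)
  if (length(real) != length(pseudo)) stopf("real and pseudo lengths differ")
  if (length(real) < 3L) stopf("need at least 3 pairs")
  if (!all(is.finite(c(real, pseudo)))) stopf("non-finite summary values")
  d <- real - pseudo
  degenerate <- FALSE
  if (all(d == 0)) {
    t_stat <- 0; p <- 1
  } else if (stats::sd(d) <= 1e-12 * max(abs(d))) {
    t_stat <- Inf * sign(mean(d)); p <- 0; degenerate <- TRUE
  } else {
    tt <- stats::t.test(real, pseudo, paired = TRUE, alternative = "two.sided")
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(
      real_values = real, pseudo_values = pseudo,
      t_stat = t_stat, df = length(d) - 1L, p_value = p,
      mean_diff = mean(d), pairing = pairing, seed = seed,
      degenerate = degenerate
    ),
    class = "surrogate_comparison"
  )
}

#' @export
print.surrogate_comparison <- function(x, ...) {
  cat(sprintf(
    "<surrogate_comparison> n = %d, mean real %.4g vs pseudo %.4g, t(%d) = %.3f, p = %.3g\n",
    length(x$real_values), mean(x$real_values), mean(x$pseudo_values),
    x$df, x$t_stat, x$p_value
  ))
  invisible(x)
}

#' Run the full surrogate validation on a set of dyads
#'
#' Builds derangement pseudo-dyads, computes the chosen per-dyad synchrony
#' summary for real and pseudo recordings, and returns the paired
#' comparison. With `n_shuffles > 1`, the pseudo summary of each dyad is
#' averaged over repeated independent shuffles before testing.
#'
#' @param dyads list of [dyad_recording()]s.
#' @param measure `"cwt"` (mean head coherence) or `"gcwt"` (mean GCWT
#'   magnitude).
#' @param seed seed for the shuffle(s).
#' @param n_shuffles number of independent derangements to average over.
#' @param ... passed to [gcwt_dyad()] when `measure = "gcwt"` (for example
#'   `keypoint_set`).
#' @return A `surrogate_comparison` (see [paired_real_vs_pseudo()]).
#' @export
surrogate_validation <- function(dyads, measure = c("cwt", "gcwt"),
                                 seed = NULL, n_shuffles = 1L, ...) {
  measure <- match.arg(measure)
  summarize <- function(d) {
    if (measure == "cwt") dyad_head_coherence(d)$mean_coherence
    else gcwt_dyad(d, ...)$mean_magnitude
  }
  real <- vapply(dyads, summarize, numeric(1))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_shuffles))
  pseudo_mat <- matrix(0, length(dyads), n_shuffles)
  pairing <- NULL
  for (s in seq_len(n_shuffles)) {
    pd <- make_pseudo_dyads(dyads, seed = seeds[s])
    if (s == 1L) pairing <- attr(pd, "pairing")
    pseudo_mat[, s] <- vapply(pd, summarize, numeric(1))
  }
  paired_real_vs_pseudo(real, rowMeans(pseudo_mat),
                        pairing = pairing, seed = seed)
}

#' Spearman correlations of a synchrony summary with quality subscales
#'
#' Spearman rank correlation (average ranks for ties) of a per-dyad
#' synchrony summary against each of the seven interaction-quality
#' subscales, with two-tailed p-values (exact for n < 10 when there are no
#' ties, asymptotic otherwise). When a second summary vector is supplied, a
#' cross-method row (`subscale = "cross_method"`) correlating the two
#' summaries is appended. No multiple-testing correction is applied by
#' default; `adjust = "holm"` is available.
#'
#' @param summaries named or plain numeric vector of per-dyad summaries,
#'   aligned with `scores$dyad_id` (alignment is checked when `summaries`
#'   carries names).
#' @param scores data frame with `dyad_id` and the seven [CIB_SUBSCALES]
#'   columns, each in `[1, 5]`.
#' @param other optional second summary vector (for example GCWT magnitude
#'   against CWT coherence).
#' @param adjust p-value adjustment across the subscale rows: `"none"`
#'   (default) or any method of [stats::p.adjust()].
#' @return Data frame with columns `measure`, `subscale`, `rho`, `p`, `n`.
#'   A constant vector makes rho undefined; such rows carry `NA`.
#' @export
spearman_with_quality <- function(summaries, scores, other = NULL,
                                  adjust = "none") {
  check_quality_scores(scores)
  n <- nrow(scores)
  if (length(summaries) != n) stopf("summaries and scores differ in length")
  if (n < 5L) stopf("need at least 5 matched dyads")
  if (!is.null(names(summaries)) &&
      !identical(names(summaries), as.character(scores$dyad_id))) {
    stopf("summary names do not align with scores$dyad_id")
  }
  one <- function(v, w) {
    if (stats::sd(v) == 0 || stats::sd(w) == 0) {
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(v, w, method = "spearman", exact = n < 10L,
                      alternative = "two.sided")
    )
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  rows <- lapply(CIB_SUBSCALES, function(sc) {
    r <- one(summaries, scores[[sc]])
    data.frame(measure = "summary", subscale = sc, rho = r["rho"], p = r["p"],
               n = n, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  if (!is.null(other)) {
    if (length(other) != n) stopf("second summary length mismatch")
    r <- one(summaries, other)
    out <- rbind(out, data.frame(measure = "cross_method",
                                 subscale = "cross_method",
                                 rho = r["rho"], p = r["p"], n = n,
                                 row.names = NULL))
  }
  rownames(out) <- NULL
  out
}

check_quality_scores <- function(scores) {
  missing_cols <- setdiff(c("dyad_id", CIB_SUBSCALES), names(scores))
  if (length(missing_cols) > 0) {
    stopf("quality scores lack columns: %s", paste(missing_cols, collapse = ", "))
  }
  for (sc in CIB_SUBSCALES) {
    if (any(!is.finite(scores[[sc]])) || any(scores[[sc]] < 1 | scores[[sc]] > 5)) {
      stopf("subscale '%s' has values outside [1, 5]", sc)
    }
  }
  invisible(TRUE)
}

#' Read / write a quality-scores table
#'
#' CSV with columns `dyad_id` plus the seven [CIB_SUBSCALES], scores in
#' `[1, 5]`.
#'
#' @param path CSV path.
#' @return `read_quality_csv`: validated data frame. `write_quality_csv`:
#'   `path`, invisibly.
#' @export
read_quality_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_quality_scores(df)
  df
}

#' @rdname read_quality_csv
#' @param scores data frame with `dyad_id` and subscale columns.
#' @export
write_quality_csv <- function(scores, path) {
  check_quality_scores(scores)
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
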