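#' Termination efficiency from Northern-blot band intensities
#'
#' For a dual-reporter construct probed for the upstream gene, the
#' monocistronic band is the prematurely terminated transcript and the
#' bicistronic band the read-through transcript, so
#' \deqn{TE = 100 \cdot I_{mono} / (I_{mono} + I_{bi}).}
#' Scale-invariant: multiplying both intensities by any positive constant
#' leaves TE unchanged. Records with both intensities zero yield `NA` with
#' a warning.
#'
#' @param I_mono,I_bi non-negative band intensities (vectorized).
#' @return TE in percent, in `[0, 100]`.
#' @export
te_from_bands <- function(I_mono, I_bi) {
  stopifnot(length(I_mono) == length(I_bi))
  if (any(I_mono < 0 | I_bi < 0, na.rm = TRUE))
    stop("band intensities must be non-negative")
  tot <- I_mono + I_bi
  if (any(tot == 0, na.rm = TRUE))
    warning(sum(tot == 0, na.rm = TRUE),
            " record(s) with zero total intensity set to NA")
  ifelse(tot > 0, 100 * I_mono / tot, NA_real_)
}

#' Termination efficiency from relative qPCR levels
#'
#' Maps the ratio of downstream (`mcherry`) to upstream (`fbfp`) relative
#' transcript levels to a termination efficiency:
#' \deqn{TE = 100 (1 - rel_{mcherry} / rel_{fbfp}),}
#' clipped into `[0, 100]`. Ratios above 1 (downstream apparently more
#' abundant, i.e. measurement noise) clip to 0 and are flagged in the
#' `clipped` attribute.
#'
#' @param rel_fbfp,rel_mcherry positive relative levels (vectorized);
#'   `rel_fbfp <= 0` is an error.
#' @return TE in percent with a logical `clipped` attribute.
#' @export
te_from_qpcr <- function(rel_fbfp, rel_mcherry) {
  stopifnot(length(rel_fbfp) == length(rel_mcherry))
  if (any(rel_fbfp <= 0, na.rm = TRUE))
    stop("rel_fbfp must be positive")
  te <- 100 * (1 - rel_mcherry / rel_fbfp)
  clipped <- te < 0 | te > 100
  te <- pmin(pmax(te, 0), 100)
  attr(te, "clipped") <- clipped
  te
}

#' Relative transcript level from Ct values
#'
#' Reference-gene normalized relative abundance,
#' `efficiency^(ref_Ct - target_Ct)`: a target amplifying 1 cycle later
#' than the reference at perfect doubling is at relative level 0.5.
#'
#' @param target_Ct,ref_Ct threshold cycles (vectorized).
#' @param efficiency per-cycle amplification factor (2 = perfect doubling).
#' @return Relative level (fold of reference).
#' @export
relative_level <- function(target_Ct, ref_Ct, efficiency = 2.0) {
  stopifnot(efficiency > 1)
  efficiency^(ref_Ct - target_Ct)
}

#' Aggregate per-replicate termination efficiencies per construct
#'
#' Northern mode takes a band-intensity table (columns `construct_id`,
#' `probe`, `I_mono`, `I_bi`, `replicate`), computes per-replicate TE from
#' the upstream-probe (`fbfp`) lanes only, and reports the per-construct
#' mean and sample standard deviation (n-1 denominator). qPCR mode takes a
#' table with columns `construct_id`, `replicate`, `rel_fbfp`,
#' `rel_mcherry`. Constructs with a single usable replicate get sd 0 and
#' `single_replicate = TRUE`.
#'
#' @param records data frame as above.
#' @param method `"northern"` or `"qpcr"`.
#' @return data frame: construct_id, te_percent, sd_percent, method,
#'   n_replicates, single_replicate.
#' @export
aggregate_te <- function(records, method = c("northern", "qpcr")) {
  method <- match.arg(method)
  records <- as.data.frame(records)
  if (method == "northern") {
    if ("probe" %in% names(records))
      records <- records[records$probe == "fbfp", , drop = FALSE]
    te <- te_from_bands(records$I_mono, records$I_bi)
  } else {
    te <- as.numeric(te_from_qpcr(records$rel_fbfp, records$rel_mcherry))
  }
  keep <- !is.na(te)
  te <- te[keep]
  id <- records$construct_id[keep]
  out <- do.call(rbind, lapply(split(te, id), function(v) {
    data.frame(te_percent = mean(v),
               sd_percent = if (length(v) >= 2) stats::sd(v) else 0,
               n_replicates = length(v),
               single_replicate = length(v) < 2)
  }))
  data.frame(construct_id = rownames(out), te_percent = out$te_percent,
             sd_percent = out$sd_percent, method = method,
             n_replicates = out$n_replicates,
             single_replicate = out$single_replicate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation and least-squares line
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-degenerate.
#' @return list: `r`, `r2`, `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = r, r2 = r^2, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(x))
}

#' Log2 fold change of upstream over downstream transcript level
#' @param upstream_level,downstream_level positive levels (vectorized).
#' @return log2(upstream / downstream).
#' @export
log2_fold_change <- function(upstream_level, downstream_level) {
  if (any(upstream_level <= 0 | downstream_level <= 0, na.rm = TRUE))
    stop("levels must be positive")
  log2(upstream_level / downstream_level)
}
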