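# Fast-exchange titration analysis: peak matching, chemical shift
# perturbations, significance thresholds, trajectory comparison, fold
# assessment and variant comparison.
#
# The combined amide CSP uses the conventional 1/5 nitrogen scaling:
#   CSP = sqrt( (dN/5)^2 + dH^2 )   [ppm]
# so that 15N changes, spread over a ~5x wider ppm range, are weighted
# comparably to 1H changes.  The same scaled metric is used as the distance
# for peak matching and as the 2D shift-vector space (dH, dN/5) for
# trajectory cosines.

N_SCALE <- 5

csp_distance <- function(d_h, d_n) sqrt((d_n / N_SCALE)^2 + d_h^2)

#' Titration series
#'
#' An ordered series of peak lists at increasing ligand:protein molar
#' ratios; the first point must be the apo spectrum (ratio 0).
#'
#' @param points List of [peak_list()]s, one per titration point.
#' @param ratios Ligand:protein molar ratios, first 0, strictly increasing.
#' @param protein_conc Protein concentration (mM).
#' @param ligand_id Ligand identifier string.
#' @return A `titration_series` object.
#' @export
titration_series <- function(points, ratios, protein_conc = NA_real_,
                             ligand_id = NA_character_) {
  if (length(points) != length(ratios))
    nd_stop("nmrdomain_value_error", "one ratio per titration point required")
  if (length(ratios) < 1L || ratios[1] != 0)
    nd_stop("nmrdomain_value_error",
            "first titration point must be apo (molar ratio 0)")
  if (any(diff(ratios) <= 0))
    nd_stop("nmrdomain_value_error", "molar ratios must be strictly increasing")
  structure(list(points = points, ratios = as.numeric(ratios),
                 protein_conc = protein_conc, ligand_id = ligand_id),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series%s: %d points at ratios %s\n",
              if (is.na(x$ligand_id)) "" else paste0(" (", x$ligand_id, ")"),
              length(x$points), paste(x$ratios, collapse = ", ")))
  invisible(x)
}

#' Match amide peaks between two peak lists
#'
#' By default peaks are paired by residue identity (assigned lists); pairs
#' whose combined-scaled distance exceeds `tol` are kept but flagged as
#' "jumps" (possible exchange-regime changes or mis-tracking).  A
#' nearest-neighbour mode pairs unassigned lists greedily by smallest scaled
#' distance within `tol`, ties broken by lowest residue number.
#'
#' @param a,b [peak_list()]s.
#' @param tol Distance tolerance in ppm on the combined scale (> 0).
#' @param method `"residue"` or `"nearest"`.
#' @return A `peak_match` list: `pairs` (data frame with positions,
#'   `distance`, `jump`), `unmatched_a`, `unmatched_b`.
#' @export
match_peaks <- function(a, b, tol = 0.15, method = c("residue", "nearest")) {
  method <- match.arg(method)
  if (!is.numeric(tol) || tol <= 0)
    nd_stop("nmrdomain_value_error", "tol must be > 0")
  if (nrow(a) == 0L || nrow(b) == 0L)
    nd_stop("nmrdomain_value_error", "peak lists must be non-empty")
  if (method == "residue") {
    shared <- intersect(a$residue_number, b$residue_number)
    ia <- match(shared, a$residue_number); ib <- match(shared, b$residue_number)
    d <- csp_distance(b$h_ppm[ib] - a$h_ppm[ia], b$n_ppm[ib] - a$n_ppm[ia])
    pairs <- data.frame(residue_number = shared,
                        h_a = a$h_ppm[ia], n_a = a$n_ppm[ia],
                        h_b = b$h_ppm[ib], n_b = b$n_ppm[ib],
                        distance = d, jump = d > tol)
    un_a <- setdiff(a$residue_number, shared)
    un_b <- setdiff(b$residue_number, shared)
  } else {
    dm <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      csp_distance(b$h_ppm[j] - a$h_ppm[i], b$n_ppm[j] - a$n_ppm[i]))
    pairs_idx <- list()
    repeat {
      if (all(!is.finite(dm)) || min(dm, na.rm = TRUE) > tol) break
      cand <- which(dm == min(dm, na.rm = TRUE), arr.ind = TRUE)
      cand <- cand[order(a$residue_number[cand[, 1]]), , drop = FALSE]
      i <- cand[1, 1]; j <- cand[1, 2]
      pairs_idx[[length(pairs_idx) + 1L]] <- c(i, j)
      dm[i, ] <- Inf; dm[, j] <- Inf
    }
    if (length(pairs_idx) > 0L) {
      m <- do.call(rbind, pairs_idx)
      d <- csp_distance(b$h_ppm[m[, 2]] - a$h_ppm[m[, 1]],
                        b$n_ppm[m[, 2]] - a$n_ppm[m[, 1]])
      pairs <- data.frame(residue_number = a$residue_number[m[, 1]],
                          h_a = a$h_ppm[m[, 1]], n_a = a$n_ppm[m[, 1]],
                          h_b = b$h_ppm[m[, 2]], n_b = b$n_ppm[m[, 2]],
                          distance = d, jump = d > tol)
      un_a <- setdiff(a$residue_number, a$residue_number[m[, 1]])
      un_b <- setdiff(b$residue_number, b$residue_number[m[, 2]])
    } else {
      pairs <- data.frame(residue_number = integer(0), h_a = numeric(0),
                          n_a = numeric(0), h_b = numeric(0),
                          n_b = numeric(0), distance = numeric(0),
                          jump = logical(0))
      un_a <- a$residue_number; un_b <- b$residue_number
    }
  }
  pairs <- pairs[order(pairs$residue_number), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched_a = sort(un_a),
                 unmatched_b = sort(un_b), tol = tol, method = method),
            class = "peak_match")
}

#' Compute combined 1H/15N chemical shift perturbations
#'
#' For every residue shared between the apo and bound peak lists,
#' `d_h = h_bound - h_apo`, `d_n = n_bound - n_apo` and
#' `csp = sqrt((d_n/5)^2 + d_h^2)`.  Applied to a [titration_series()], the
#' apo point is compared to the final (highest-ratio) point; intermediate
#' points serve trajectory checks only.
#'
#' @param apo Apo [peak_list()], or a [titration_series()].
#' @param bound Bound-state [peak_list()] (ignored for a series).
#' @param endpoint_ratio Molar ratio of the bound point, recorded in the
#'   profile.
#' @return A `csp_profile` data frame: `residue_number`, `d_h`, `d_n`,
#'   `csp`, with attribute `endpoint_ratio`.
#' @export
compute_csp <- function(apo, bound = NULL, endpoint_ratio = NA_real_)
  UseMethod("compute_csp")

#' @export
compute_csp.titration_series <- function(apo, bound = NULL,
                                         endpoint_ratio = NA_real_) {
  n <- length(apo$points)
  compute_csp(apo$points[[1]], apo$points[[n]],
              endpoint_ratio = apo$ratios[n])
}

#' @export
compute_csp.peak_list <- function(apo, bound = NULL,
                                  endpoint_ratio = NA_real_) {
  shared <- intersect(apo$residue_number, bound$residue_number)
  if (length(shared) == 0L)
    nd_stop("nmrdomain_value_error", "no shared residues between peak lists")
  ia <- match(shared, apo$residue_number)
  ib <- match(shared, bound$residue_number)
  d_h <- bound$h_ppm[ib] - apo$h_ppm[ia]
  d_n <- bound$n_ppm[ib] - apo$n_ppm[ia]
  out <- data.frame(residue_number = shared, d_h = d_h, d_n = d_n,
                    csp = csp_distance(d_h, d_n))
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "endpoint_ratio") <- endpoint_ratio
  class(out) <- c("csp_profile", "data.frame")
  out
}

# Population (n-divisor) standard deviation: the spread statistic used for
# CSP significance thresholds.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Select significantly perturbed residues
#'
#' The threshold is computed from all CSP values in the profile as the mean
#' (`"mean"`), twice the population standard deviation (`"two_sd"`), or
#' their sum (`"mean_plus_two_sd"`, the default); residues strictly above
#' the threshold are significant.
#'
#' @param profile A `csp_profile` with at least 3 residues.
#' @param mode Threshold mode.
#' @return A `csp_significance` list: `mode`, `threshold`,
#'   `significant_residues`, plus the profile `mean` and `sd` used.
#' @export
csp_significance <- function(profile,
                             mode = c("mean_plus_two_sd", "two_sd", "mean")) {
  mode <- match.arg(mode)
  if (nrow(profile) < 3L)
    nd_stop("nmrdomain_value_error",
            "need >= 3 residues for a significance threshold")
  m <- mean(profile$csp); s <- pop_sd(profile$csp)
  threshold <- switch(mode, mean = m, two_sd = 2 * s,
                      mean_plus_two_sd = m + 2 * s)
  structure(list(mode = mode, threshold = threshold,
                 significant_residues =
                   profile$residue_number[profile$csp > threshold],
                 mean = m, sd = s, n = nrow(profile)),
            class = "csp_significance")
}

#' @export
print.csp_significance <- function(x, ...) {
  cat(sprintf("CSP significance (%s): threshold %.4f ppm over %d residues\n",
              x$mode, x$threshold, x$n))
  if (length(x$significant_residues) == 0L) cat("No significant residues\n")
  else cat("Significant residues:",
           paste(x$significant_residues, collapse = ", "), "\n")
  invisible(x)
}

#' Per-residue cosine similarity of CSP trajectories
#'
#' In the fast-exchange regime a residue's peak moves along a straight line
#' between free and bound positions, so two titrations that engage the same
#' site produce parallel shift vectors even when their extents differ.  The
#' cosine is taken between the vectors `(d_h, d_n/5)` of the two profiles;
#' residues with a zero vector in either profile are skipped with a notice.
#'
#' @param a,b `csp_profile`s over overlapping residues.
#' @param mode Significance mode used for the summary subset.
#' @return A `trajectory_similarity` data frame (`residue_number`,
#'   `cosine`) with attribute `summary`: the median cosine over residues
#'   significant in either profile (over all compared residues if neither
#'   profile has significant ones).
#' @export
trajectory_similarity <- function(a, b,
                                  mode = c("mean_plus_two_sd", "two_sd",
                                           "mean")) {
  mode <- match.arg(mode)
  shared <- intersect(a$residue_number, b$residue_number)
  if (length(shared) == 0L)
    nd_stop("nmrdomain_value_error", "no shared residues")
  ia <- match(shared, a$residue_number); ib <- match(shared, b$residue_number)
  va <- cbind(a$d_h[ia], a$d_n[ia] / N_SCALE)
  vb <- cbind(b$d_h[ib], b$d_n[ib] / N_SCALE)
  na_ <- sqrt(rowSums(va^2)); nb_ <- sqrt(rowSums(vb^2))
  zero <- na_ == 0 | nb_ == 0
  if (any(zero)) {
    message(sprintf("trajectory_similarity: skipping %d residue(s) with zero shift vector",
                    sum(zero)))
    shared <- shared[!zero]; va <- va[!zero, , drop = FALSE]
    vb <- vb[!zero, , drop = FALSE]; na_ <- na_[!zero]; nb_ <- nb_[!zero]
  }
  if (length(shared) == 0L)
    nd_stop("nmrdomain_value_error", "no residues with nonzero shift vectors")
  cosine <- rowSums(va * vb) / (na_ * nb_)
  out <- data.frame(residue_number = shared, cosine = cosine)
  sig <- union(
    if (nrow(a) >= 3L) csp_significance(a, mode)$significant_residues
    else integer(0),
    if (nrow(b) >= 3L) csp_significance(b, mode)$significant_residues
    else integer(0))
  subset <- if (length(intersect(sig, shared)) > 0L)
    out$cosine[out$residue_number %in% sig] else out$cosine
  attr(out, "summary") <- stats::median(subset)
  class(out) <- c("trajectory_similarity", "data.frame")
  out
}

#' Assess foldedness from amide peak dispersion
#'
#' A folded domain disperses amide protons well beyond the random-coil
#' window; a collapsed (unfolded) species shows a confined distribution
#' around ~8.3 ppm.  The verdict is `folded` iff the 1H shift range exceeds
#' `range_min` AND the 1H standard deviation exceeds `sd_min`.
#'
#' @param peaks A [peak_list()] with at least 10 peaks.
#' @param range_min Minimum 1H range (ppm) for a folded call (default 1.5).
#' @param sd_min Minimum 1H standard deviation (ppm) for a folded call
#'   (default 0.35).
#' @return A `fold_assessment` list: `verdict` (`"folded"`/`"collapsed"`),
#'   `h_range`, `h_sd`, `n_peaks` and the thresholds used.
#' @export
assess_fold <- function(peaks, range_min = 1.5, sd_min = 0.35) {
  if (nrow(peaks) < 10L)
    nd_stop("nmrdomain_value_error",
            "need >= 10 peaks to assess fold (got %d)", nrow(peaks))
  h_range <- diff(range(peaks$h_ppm))
  h_sd <- stats::sd(peaks$h_ppm)
  structure(list(
    verdict = if (h_range > range_min && h_sd > sd_min) "folded"
              else "collapsed",
    h_range = h_range, h_sd = h_sd, n_peaks = nrow(peaks),
    range_min = range_min, sd_min = sd_min),
    class = "fold_assessment")
}

#' @export
print.fold_assessment <- function(x, ...) {
  cat(sprintf("Fold assessment: %s (1H range %.2f ppm, sd %.3f ppm, %d peaks)\n",
              x$verdict, x$h_range, x$h_sd, x$n_peaks))
  invisible(x)
}

#' Compare variant binding against the wild type
#'
#' Quantifies how a protein variant's CSP response compares to the wild
#' type over the wild type's significantly perturbed residues:
#' `extent_ratio` is the ratio of summed variant to summed wild-type CSPs
#' over those residues; `trajectory_summary` is the median shift-vector
#' cosine over them.  The verdict is `abolished` when the extent drops
#' below 0.1, `reduced` for extents in [0.1, 0.7) with conserved
#' trajectories (summary > 0.8), `wt_like` for extents >= 0.7 with
#' conserved trajectories, and `nonspecific` otherwise (shifts present but
#' along different directions).
#'
#' @param wt_profile,variant_profile `csp_profile`s on overlapping
#'   residues.
#' @param mode Significance mode for selecting wild-type binding residues.
#' @return A `variant_comparison` list: `extent_ratio`,
#'   `trajectory_summary`, `verdict`, `wt_significant`.
#' @export
compare_variant_binding <- function(wt_profile, variant_profile,
                                    mode = c("mean_plus_two_sd", "two_sd",
                                             "mean")) {
  mode <- match.arg(mode)
  sig <- csp_significance(wt_profile, mode)$significant_residues
  sig <- intersect(sig, variant_profile$residue_number)
  if (length(sig) == 0L)
    nd_stop("nmrdomain_value_error",
            "no significantly perturbed wild-type residues shared with the variant profile")
  iw <- match(sig, wt_profile$residue_number)
  iv <- match(sig, variant_profile$residue_number)
  extent_ratio <- sum(variant_profile$csp[iv]) / sum(wt_profile$csp[iw])
  traj <- tryCatch({
    ts <- trajectory_similarity(wt_profile, variant_profile, mode = mode)
    keep <- ts$residue_number %in% sig
    if (any(keep)) stats::median(ts$cosine[keep]) else NA_real_
  }, error = function(e) NA_real_)
  verdict <- if (extent_ratio < 0.1) "abolished"
    else if (extent_ratio < 0.7 && isTRUE(traj > 0.8)) "reduced"
    else if (extent_ratio >= 0.7 && isTRUE(traj > 0.8)) "wt_like"
    else "nonspecific"
  structure(list(extent_ratio = extent_ratio, trajectory_summary = traj,
                 verdict = verdict, wt_significant = sig, mode = mode),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat(sprintf("Variant binding: %s (extent ratio %.3f, trajectory cosine %s over residues %s)\n",
              x$verdict, x$extent_ratio,
              if (is.na(x$trajectory_summary)) "NA"
              else sprintf("%.3f", x$trajectory_summary),
              paste(x$wt_significant, collapse = ", ")))
  invisible(x)
}

#' @export
plot.csp_profile <- function(x, significance = NULL, ...) {
  graphics::barplot(x$csp, names.arg = x$residue_number, xlab = "residue",
                    ylab = "CSP (ppm)", border = NA, col = "grey40", ...)
  if (!is.null(significance)) {
    graphics::abline(h = significance$threshold, col = "black")
    graphics::abline(h = significance$mean, col = "grey50", lty = 3)
  }
  invisible(x)
}
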