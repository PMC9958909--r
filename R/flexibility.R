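# Backbone flexibility from {1H}15N heteronuclear NOE ratios.
#
# The steady-state hetNOE is the intensity ratio I_sat/I_ref of an amide
# peak with and without proton saturation.  Low ratios report ps-ns
# flexibility; classification thresholds follow the common practice of
# reading ratios below 0.5 as flexible and above 0.65 as rigid, with the
# band in between left "intermediate" rather than over-claimed either way.

FLEX_LOWER <- 0.5
FLEX_UPPER <- 0.65

#' Compute heteronuclear NOE ratios from saturated/reference peak lists
#'
#' Ratios are `height_sat / height_ref` per residue shared between the two
#' lists.  Uncertainties are propagated from per-list noise estimates as
#' `|ratio| * sqrt((sigma_sat/I_sat)^2 + (sigma_ref/I_ref)^2)`; with the
#' default noise of 0 the error column is 0.
#'
#' @param sat,ref [peak_list()]s with a `height` column (saturated and
#'   reference experiment).
#' @param sigma_sat,sigma_ref Per-list noise estimates (same units as the
#'   heights).
#' @return A `hetnoe_profile` data frame: `residue_number`, `ratio`,
#'   `error`.  Residues whose reference height is zero are skipped with a
#'   warning.
#' @export
compute_hetnoe <- function(sat, ref, sigma_sat = 0, sigma_ref = 0) {
  for (pl in list(sat, ref))
    if (!"height" %in% names(pl))
      nd_stop("nmrdomain_value_error", "peak lists must carry heights")
  shared <- intersect(sat$residue_number, ref$residue_number)
  if (length(shared) == 0L)
    nd_stop("nmrdomain_value_error", "no shared residues between lists")
  hs <- sat$height[match(shared, sat$residue_number)]
  hr <- ref$height[match(shared, ref$residue_number)]
  zero <- hr == 0
  if (any(zero)) {
    nd_warn("skipping %d residue(s) with zero reference height: %s",
            sum(zero), paste(shared[zero], collapse = ", "))
    shared <- shared[!zero]; hs <- hs[!zero]; hr <- hr[!zero]
  }
  ratio <- hs / hr
  err <- abs(ratio) * sqrt((sigma_sat / hs)^2 + (sigma_ref / hr)^2)
  err[!is.finite(err)] <- 0
  hetnoe_profile(shared, ratio, err)
}

#' Construct a hetNOE profile directly from ratios
#' @param residue_number Residue numbers.
#' @param ratio hetNOE ratios (I_sat/I_ref), finite.
#' @param error Non-negative uncertainties.
#' @return A `hetnoe_profile` data frame.
#' @export
hetnoe_profile <- function(residue_number, ratio, error = 0) {
  df <- data.frame(residue_number = as.integer(residue_number),
                   ratio = as.numeric(ratio),
                   error = rep_len(as.numeric(error), length(residue_number)))
  if (any(!is.finite(df$ratio)))
    nd_stop("nmrdomain_validation_error", "ratios must be finite")
  if (any(df$error < 0))
    nd_stop("nmrdomain_validation_error", "errors must be >= 0")
  df <- df[order(df$residue_number), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hetnoe_profile", "data.frame")
  df
}

#' Classify per-residue flexibility from hetNOE ratios
#'
#' Ratios below 0.5 are `flexible`, above 0.65 `rigid`, otherwise
#' `intermediate`.
#'
#' @param profile A `hetnoe_profile`.
#' @return A `flexibility_call` data frame: `residue_number`, `ratio`,
#'   `label`.
#' @export
classify_flexibility <- function(profile) {
  if (nrow(profile) == 0L)
    nd_stop("nmrdomain_value_error", "empty hetNOE profile")
  out <- data.frame(residue_number = profile$residue_number,
                    ratio = profile$ratio,
                    label = ifelse(profile$ratio < FLEX_LOWER, "flexible",
                                   ifelse(profile$ratio > FLEX_UPPER,
                                          "rigid", "intermediate")),
                    stringsAsFactors = FALSE)
  class(out) <- c("flexibility_call", "data.frame")
  out
}

#' Rigid-core boundaries from a flexibility classification
#'
#' Returns the longest stretch of rigid residues in which interruptions
#' (non-rigid or unobserved residues) of at most `max_gap` consecutive
#' positions are tolerated, mirroring how short flexible stretches inside an
#' otherwise rigid domain do not break the core.
#'
#' @param call A `flexibility_call` from [classify_flexibility()].
#' @param max_gap Longest tolerated interruption, in residues (default 3).
#' @return `c(start, end)` of the core, or `NULL` if no residue is rigid.
#' @export
rigid_core <- function(call, max_gap = 3L) {
  if (!is_count(max_gap) || max_gap < 0L)
    nd_stop("nmrdomain_value_error", "max_gap must be a non-negative integer")
  rigid <- sort(call$residue_number[call$label == "rigid"])
  if (length(rigid) == 0L) return(NULL)
  gap_after <- diff(rigid) - 1L
  run_id <- cumsum(c(0L, gap_after > max_gap))
  spans <- vapply(split(rigid, run_id), function(r) c(min(r), max(r)),
                  numeric(2))
  best <- which.max(spans[2, ] - spans[1, ])
  c(start = unname(spans[1, best]), end = unname(spans[2, best]))
}

#' @export
print.flexibility_call <- function(x, max_gap = 3L, ...) {
  counts <- table(factor(x$label,
                         levels = c("flexible", "intermediate", "rigid")))
  cat(sprintf("Flexibility over %d residues: %d flexible, %d intermediate, %d rigid\n",
              nrow(x), counts[["flexible"]], counts[["intermediate"]],
              counts[["rigid"]]))
  core <- rigid_core(x, max_gap = max_gap)
  if (is.null(core)) cat("No rigid core\n")
  else cat(sprintf("Rigid core: residues %d-%d (gaps <= %d tolerated)\n",
                   core[["start"]], core[["end"]], max_gap))
  invisible(x)
}

#' @export
plot.hetnoe_profile <- function(x, ...) {
  graphics::plot(x$residue_number, x$ratio, pch = 16,
                 xlab = "residue", ylab = "{1H}15N hetNOE", ylim = range(
                   c(0, 1, x$ratio + x$error, x$ratio - x$error)), ...)
  graphics::arrows(x$residue_number, x$ratio - x$error,
                   x$residue_number, x$ratio + x$error,
                   angle = 90, code = 3, length = 0.02)
  graphics::abline(h = c(FLEX_LOWER, FLEX_UPPER), lty = 2, col = "grey40")
  invisible(x)
}
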