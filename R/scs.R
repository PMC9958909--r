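# Secondary chemical shifts and secondary-structure calling.
#
# Combined Ca/Cb SCS is defined as d(Ca)_obs - d(Ca)_coil minus
# d(Cb)_obs - d(Cb)_coil.  Helix formation moves Ca downfield and Cb
# upfield, so the difference amplifies both effects into a single trace:
# positive runs mark helices, negative runs mark strands.  For glycine (no
# Cb) and residues without an assigned Cb, the combined value is the Ca
# deviation alone.

#' Compute combined Ca/Cb secondary chemical shifts
#'
#' @param shifts A [shift_table()] containing `CA` (and usually `CB`)
#'   entries.
#' @param rc A random-coil reference table from [random_coil_table()].
#' @return An `scs_profile` data frame with one row per residue that has a
#'   Ca shift: `residue_number`, `residue_type`, `delta_ca`, `delta_cb`
#'   (NA where Cb is unassigned or absent) and
#'   `combined_scs = delta_ca - delta_cb` (or `delta_ca` alone where Cb is
#'   missing).
#' @export
compute_scs <- function(shifts, rc = random_coil_table()) {
  stopifnot(inherits(shifts, "shift_table"))
  ca <- shifts[shifts$atom_name == "CA", , drop = FALSE]
  cb <- shifts[shifts$atom_name == "CB", , drop = FALSE]
  if (nrow(ca) == 0L) {
    nd_warn("no CA entries in shift table; SCS profile is empty")
    out <- data.frame(residue_number = integer(0), residue_type = character(0),
                      delta_ca = numeric(0), delta_cb = numeric(0),
                      combined_scs = numeric(0))
    class(out) <- c("scs_profile", "data.frame")
    return(out)
  }
  missing_rc <- setdiff(unique(ca$residue_type), rc$residue_type)
  if (length(missing_rc) > 0L)
    nd_stop("nmrdomain_lookup_error",
            "residue type(s) absent from random-coil table: %s",
            paste(missing_rc, collapse = ", "))
  idx <- match(ca$residue_type, rc$residue_type)
  delta_ca <- ca$shift - rc$coil_ca[idx]
  cb_idx <- match(ca$residue_number, cb$residue_number)
  delta_cb <- ifelse(is.na(cb_idx), NA_real_,
                     cb$shift[cb_idx] - rc$coil_cb[idx])
  out <- data.frame(residue_number = ca$residue_number,
                    residue_type = ca$residue_type,
                    delta_ca = delta_ca,
                    delta_cb = delta_cb,
                    combined_scs = ifelse(is.na(delta_cb), delta_ca,
                                          delta_ca - delta_cb),
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rc_table") <- attr(rc, "id")
  class(out) <- c("scs_profile", "data.frame")
  out
}

#' Call secondary-structure elements from an SCS profile
#'
#' Maximal runs of at least three consecutive residues with combined SCS
#' strictly above `+threshold` are called helices; maximal runs of at least
#' four consecutive residues strictly below `-threshold` are called strands.
#' Residues missing from the profile break runs.
#'
#' @param profile An `scs_profile` from [compute_scs()].
#' @param threshold Significance threshold in ppm (> 0); default 1.
#' @param min_helix,min_strand Minimum run lengths (defaults 3 and 4).
#' @return An `sse_annotation` data frame with columns `kind` (`"helix"` or
#'   `"strand"`), `start`, `end`; non-overlapping and sorted.
#' @export
call_sse <- function(profile, threshold = 1, min_helix = 3L, min_strand = 4L) {
  if (!is.numeric(threshold) || threshold <= 0)
    nd_stop("nmrdomain_value_error", "threshold must be > 0")
  if (nrow(profile) == 0L)
    nd_stop("nmrdomain_value_error", "empty SCS profile")
  p <- profile[order(profile$residue_number), , drop = FALSE]
  sign_state <- ifelse(p$combined_scs > threshold, 1L,
                       ifelse(p$combined_scs < -threshold, -1L, 0L))
  res <- p$residue_number
  # split into runs of equal state over consecutive residue numbers
  brk <- c(TRUE, diff(res) != 1L | diff(sign_state) != 0L)
  run_id <- cumsum(brk)
  elements <- list()
  for (id in unique(run_id)) {
    sel <- run_id == id
    st <- sign_state[sel][1]
    len <- sum(sel)
    if (st == 1L && len >= min_helix)
      elements[[length(elements) + 1L]] <-
        data.frame(kind = "helix", start = min(res[sel]), end = max(res[sel]))
    else if (st == -1L && len >= min_strand)
      elements[[length(elements) + 1L]] <-
        data.frame(kind = "strand", start = min(res[sel]), end = max(res[sel]))
  }
  out <- if (length(elements) > 0L) do.call(rbind, elements)
    else data.frame(kind = character(0), start = integer(0), end = integer(0))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("sse_annotation", "data.frame")
  out
}

#' @export
print.sse_annotation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No secondary-structure elements called\n")
  } else {
    cat(sprintf("%d secondary-structure element(s) (|SCS| > %g ppm):\n",
                nrow(x), attr(x, "threshold") %||% 1))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  %-6s %d-%d (%d residues)\n", x$kind[i], x$start[i],
                  x$end[i], x$end[i] - x$start[i] + 1L))
  }
  invisible(x)
}

#' @export
plot.scs_profile <- function(x, threshold = 1, ...) {
  graphics::barplot(x$combined_scs, names.arg = x$residue_number,
                    xlab = "residue", ylab = "combined Ca/Cb SCS (ppm)",
                    border = NA,
                    col = ifelse(x$combined_scs > threshold, "firebrick",
                                 ifelse(x$combined_scs < -threshold,
                                        "steelblue", "grey60")), ...)
  graphics::abline(h = c(-threshold, threshold), lty = 2, col = "grey30")
  invisible(x)
}
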