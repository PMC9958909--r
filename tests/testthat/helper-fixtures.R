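# Shared fixture builders; everything is generated in code.

make_shift_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# shift table fixture",
               paste(names(df), collapse = "\t"),
               do.call(paste, c(unname(as.list(df)), sep = "\t"))), path)
  path
}

make_peak_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df) > 0L)
    lines <- c(lines, do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path)
  path
}

flat_peaks <- function(residues, h = 8.2, n = 119, height = NULL) {
  peak_list(residues, rep("A", length(residues)),
            rep_len(h, length(residues)), rep_len(n, length(residues)),
            height = if (!is.null(height)) rep_len(height, length(residues)))
}

# peak list with a deterministic spread of positions (no RNG)
spread_peaks <- function(residues, height = NULL) {
  k <- seq_along(residues)
  peak_list(residues, rep("L", length(residues)),
            7.0 + 0.05 * k, 108 + 0.4 * k,
            height = if (!is.null(height)) rep_len(height, length(residues)))
}

shift_profile <- function(combined, residues = seq_along(combined)) {
  # wrap a ready-made combined-SCS vector as an scs_profile
  out <- data.frame(residue_number = as.integer(residues),
                    residue_type = "A",
                    delta_ca = combined, delta_cb = NA_real_,
                    combined_scs = combined)
  class(out) <- c("scs_profile", "data.frame")
  out
}

csp_profile_from <- function(residues, d_h, d_n) {
  out <- data.frame(residue_number = as.integer(residues),
                    d_h = d_h, d_n = d_n,
                    csp = sqrt((d_n / 5)^2 + d_h^2))
  class(out) <- c("csp_profile", "data.frame")
  out
}

rate_profile_from <- function(residues, rates, experiment = "T2") {
  out <- data.frame(residue = residues, rate = rates, error = 0,
                    fit_quality = 1, flagged = FALSE)
  attr(out, "experiment") <- experiment
  class(out) <- c("rate_profile", "data.frame")
  out
}

standin_fasta <- function() {
  system.file("extdata", "Q14151_synthetic_standin.fasta",
              package = "nmrdomain")
}
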