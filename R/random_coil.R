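# Random-coil Ca/Cb reference shifts.
#
# Secondary chemical shifts are deviations from residue-specific random-coil
# values; the bundled table is a standard neutral-pH, 25 C compilation of
# coil Ca/Cb shifts in the Wishart tradition (glycine has no Cb).  Values are
# in ppm on the DSS scale.  Which coil set is used matters little for
# secondary-structure calling as long as the same table is used throughout;
# the table id is recorded so reports are self-describing.

RC_TABLES <- list(
  wishart1995 = data.frame(
    residue_type = c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y"),
    coil_ca = c(52.5, 56.0, 52.8, 54.2, 58.2, 56.6, 55.7, 45.1, 55.0, 61.1,
                55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 62.2, 57.5, 57.9),
    coil_cb = c(19.1, 30.9, 37.9, 41.1, 28.0, 29.9, 29.4,   NA, 29.0, 38.8,
                42.4, 33.1, 32.9, 39.6, 31.8, 63.8, 69.8, 32.9, 29.6, 38.8),
    stringsAsFactors = FALSE)
)

RC_CITATIONS <- c(
  wishart1995 = "random-coil Ca/Cb shifts, neutral pH / 25 C compilation (DSS-referenced)")

#' Bundled random-coil chemical-shift table
#'
#' @param id Table identifier; currently `"wishart1995"`.
#' @return A data frame with columns `residue_type`, `coil_ca`, `coil_cb`
#'   (NA for glycine), with attributes `id` and `citation`.
#' @export
random_coil_table <- function(id = "wishart1995") {
  if (!id %in% names(RC_TABLES))
    nd_stop("nmrdomain_lookup_error",
            "unknown random-coil table '%s' (available: %s)",
            id, paste(names(RC_TABLES), collapse = ", "))
  tab <- RC_TABLES[[id]]
  attr(tab, "id") <- id
  attr(tab, "citation") <- unname(RC_CITATIONS[id])
  tab
}
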