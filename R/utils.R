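# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers/tests can distinguish failure modes.
nd_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "nmrdomain_error")))
}

nd_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
# All generators funnel through this, so they are pure functions of
# (parameters, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    nd_stop("nmrdomain_value_error", "seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

AA_ONE <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

check_residue_types <- function(x, what = "residue_type") {
  bad <- setdiff(unique(x), AA_ONE)
  if (length(bad) > 0L)
    nd_stop("nmrdomain_alphabet_error",
            "unknown %s code(s): %s", what, paste(bad, collapse = ", "))
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
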