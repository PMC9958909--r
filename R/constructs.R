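# Expression-construct assembly and theoretical masses.
#
# Constructs are numbered in full-length (UniProt) coordinates, 1-based and
# inclusive.  Cloning artefacts left at the N-terminus after tag cleavage
# (e.g. a Gly-Ala-Met scar) are carried as a prefix whose residues take the
# numbers immediately preceding the native start, so that a "GAM" prefix on a
# construct starting at residue 21 is numbered 18, 19, 20.

# Average residue masses (Da): amino acid minus one water, standard average
# atomic weights, free termini, reduced cysteines, no modifications.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)

WATER_MASS_DA <- 18.01524

seq_chars <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    nd_stop("nmrdomain_value_error", "sequence must be a single string")
  strsplit(toupper(sequence), "")[[1]]
}

#' Assemble an expression construct in full-length numbering
#'
#' Extracts an inclusive residue range from a full-length protein sequence and
#' prepends an artificial N-terminal scar (such as the Gly-Ala-Met left by TEV
#' cleavage).  Prefix residues are numbered consecutively so that they end at
#' `start - 1`, keeping every residue number in the construct identical to its
#' full-length coordinate.
#'
#' @param full_sequence Full-length protein sequence, one-letter codes.
#' @param start,end Inclusive native range in full-length numbering (1-based).
#' @param prefix Artificial N-terminal residues (one-letter string), possibly
#'   empty.
#' @param parent_id Optional identifier of the parent sequence (e.g. a UniProt
#'   accession).
#' @return A `protein_construct` object: a list with `parent_id`,
#'   `native_start`, `native_end`, `prefix`, `prefix_numbers`, `sequence`
#'   (prefix + native span) and `numbers` (one residue number per character of
#'   `sequence`).
#' @examples
#' fl <- paste(rep("ACDEFGHIKL", 8), collapse = "")
#' cons <- assemble_construct(fl, start = 21, end = 70, prefix = "GAM")
#' cons$numbers[1:4]   # 18 19 20 21
#' @export
assemble_construct <- function(full_sequence, start, end, prefix = "",
                               parent_id = NA_character_) {
  chars <- seq_chars(full_sequence)
  check_residue_types(chars, "sequence")
  if (!is_count(start) || !is_count(end))
    nd_stop("nmrdomain_value_error", "start and end must be integers")
  if (start < 1L || end > length(chars) || start > end)
    nd_stop("nmrdomain_bounds_error",
            "range [%d, %d] outside sequence of length %d",
            start, end, length(chars))
  pre <- seq_chars(prefix)
  if (length(pre) > 0L) check_residue_types(pre, "prefix")
  if (length(pre) >= start)
    nd_stop("nmrdomain_numbering_error",
            "prefix of %d residues does not fit before native start %d (numbering would drop below 1)",
            length(pre), start)
  prefix_numbers <- if (length(pre) > 0L)
    seq.int(start - length(pre), start - 1L) else integer(0)
  structure(list(
    parent_id = parent_id,
    native_start = as.integer(start),
    native_end = as.integer(end),
    prefix = prefix,
    prefix_numbers = prefix_numbers,
    sequence = paste(c(pre, chars[start:end]), collapse = ""),
    numbers = c(prefix_numbers, seq.int(start, end))
  ), class = "protein_construct")
}

#' @export
print.protein_construct <- function(x, ...) {
  cat(sprintf("Protein construct%s: residues %d-%d%s (%d aa, %.2f kDa)\n",
              if (is.na(x$parent_id)) "" else paste0(" [", x$parent_id, "]"),
              x$numbers[1], x$native_end,
              if (nzchar(x$prefix)) paste0(", prefix ", x$prefix) else "",
              nchar(x$sequence), average_mass(x)))
  cat(x$sequence, "\n")
  invisible(x)
}

#' Theoretical average molecular mass of a protein chain
#'
#' Sum of average residue masses plus one water (free amino and carboxy
#' termini, reduced cysteines, no modifications or isotope labelling),
#' reported in kDa at full precision.
#'
#' @param sequence One-letter protein sequence or a [assemble_construct()]
#'   result.
#' @return Mass in kDa.
#' @examples
#' average_mass("G") * 1000  # 75.07 Da
#' @export
average_mass <- function(sequence) UseMethod("average_mass")

#' @export
average_mass.protein_construct <- function(sequence)
  average_mass(sequence$sequence)

#' @export
average_mass.character <- function(sequence) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L)
    nd_stop("nmrdomain_value_error", "empty sequence")
  check_residue_types(chars, "sequence")
  (sum(AA_RESIDUE_MASS[chars]) + WATER_MASS_DA) / 1000
}

#' Count non-proline residues in a sequence range
#'
#' Prolines carry no backbone amide proton, so the number of non-proline
#' residues in a construct is the number of observable backbone amides.
#'
#' @param full_sequence One-letter protein sequence.
#' @param start,end Inclusive range (defaults to the whole sequence).
#' @return Integer count of residues in `[start, end]` that are not `P`.
#' @export
count_non_proline <- function(full_sequence, start = 1L,
                              end = nchar(full_sequence)) {
  chars <- seq_chars(full_sequence)
  if (!is_count(start) || !is_count(end) ||
      start < 1L || end > length(chars) || start > end)
    nd_stop("nmrdomain_bounds_error",
            "invalid range [%s, %s] for sequence of length %d",
            format(start), format(end), length(chars))
  sum(chars[start:end] != "P")
}

#' Mass of an n-mer
#'
#' @param monomer_mass Monomer mass in kDa.
#' @param n Oligomeric state (>= 1).
#' @return `n * monomer_mass` in kDa.
#' @export
oligomer_mass <- function(monomer_mass, n) {
  if (!is_count(n) || n < 1L)
    nd_stop("nmrdomain_value_error", "n must be an integer >= 1")
  if (!is.numeric(monomer_mass) || monomer_mass <= 0)
    nd_stop("nmrdomain_value_error", "monomer_mass must be positive")
  n * monomer_mass
}
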