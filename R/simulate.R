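# Seeded synthetic-data generators with known ground truth.
#
# Every generator is a pure function of (parameters, seed): the caller's RNG
# stream is left untouched and repeated calls with the same seed reproduce
# the same output bit for bit.  Two of the generators are physical oracles:
# the single-site fast-exchange binding isotherm behind gen_titration(), and
# the model-free (Lipari-Szabo) 15N relaxation rates behind
# simulate_relaxation_rates(), which validate the titration and
# correlation-time analyses against independent physics.

# physical constants (SI)
.MU0_OVER_4PI <- 1e-7
.HBAR <- 1.054571817e-34
.GAMMA_H <- 2.6752218744e8     # rad s^-1 T^-1
.GAMMA_N <- -2.7126e7          # rad s^-1 T^-1 (negative for 15N)

#' Fraction of protein bound in a single-site equilibrium
#'
#' Exact solution of the 1:1 binding quadratic,
#' `f_b = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`,
#' bounded in [0, 1]; monotonically increasing in ligand concentration and
#' decreasing in Kd.
#'
#' @param p Total protein concentration (mM), > 0.
#' @param l Total ligand concentration (mM), >= 0 (vectorized).
#' @param kd Dissociation constant (mM), > 0.
#' @return Fraction bound.
#' @export
fraction_bound <- function(p, l, kd) {
  if (!is.numeric(p) || p <= 0) nd_stop("nmrdomain_value_error", "p must be > 0")
  if (any(l < 0)) nd_stop("nmrdomain_value_error", "l must be >= 0")
  if (!is.numeric(kd) || kd <= 0)
    nd_stop("nmrdomain_value_error", "kd must be > 0")
  s <- p + l + kd
  fb <- (s - sqrt(s^2 - 4 * p * l)) / (2 * p)
  pmin(pmax(fb, 0), 1)
}

#' Generate a synthetic amide peak list
#'
#' Random but seeded amide positions, drawn from the typical folded-protein
#' window (1H around 8.3 +/- sd, 15N around 119 +/- sd).
#'
#' @param residues Residue numbers.
#' @param seed RNG seed.
#' @param h_center,h_sd,n_center,n_sd Position distribution parameters
#'   (ppm).
#' @param height Peak height assigned to every peak.
#' @return A [peak_list()].
#' @export
gen_peaklist <- function(residues, seed = NULL, h_center = 8.3, h_sd = 0.5,
                         n_center = 119, n_sd = 4, height = 100) {
  with_seed(seed, {
    n <- length(residues)
    peak_list(residues,
              sample(setdiff(AA_ONE, "P"), n, replace = TRUE),
              stats::rnorm(n, h_center, h_sd),
              stats::rnorm(n, n_center, n_sd),
              height = rep(height, n))
  })
}

#' Simulate a fast-exchange titration series
#'
#' At each ligand:protein molar ratio the binding residues move along the
#' straight line from their free to their bound position by the fraction
#' bound from the single-site isotherm (the textbook fast-exchange limit:
#' one population-weighted peak).  All peaks at all points are jittered by
#' Gaussian noise of `noise_ppm` in 1H and `5 * noise_ppm` in 15N so both
#' axes contribute equally on the combined scale.  Defaults reflect a
#' typical micromolar-affinity nucleic-acid titration followed by HSQCs:
#' 0.1 mM protein, Kd = 0.01 mM, ratios 0 / 0.5 / 1 / 1.85 / 4 / 6.
#'
#' @param base_peaks Apo [peak_list()].
#' @param binders Data frame with columns `residue_number`, `d_h_max`,
#'   `d_n_max`: the endpoint (fully bound) shift changes of each binding
#'   residue in ppm.  Must be a subset of `base_peaks`.
#' @param kd Dissociation constant (mM).
#' @param protein_conc Protein concentration (mM).
#' @param ratios Molar ratios; must start at 0.
#' @param noise_ppm 1H jitter SD (ppm); 15N jitter is 5x this.
#' @param seed RNG seed.
#' @return A [titration_series()] with attribute `truth`: the binder table,
#'   `kd`, `protein_conc` and the fraction bound at each ratio.
#' @export
gen_titration <- function(base_peaks, binders, kd = 0.01, protein_conc = 0.1,
                          ratios = c(0, 0.5, 1, 1.85, 4, 6),
                          noise_ppm = 0, seed = NULL) {
  if (length(ratios) < 1L || ratios[1] != 0)
    nd_stop("nmrdomain_value_error", "ratios must start at 0 (apo)")
  if (!all(binders$residue_number %in% base_peaks$residue_number))
    nd_stop("nmrdomain_value_error",
            "binding residues must be a subset of the base peak list")
  fb <- fraction_bound(protein_conc, ratios * protein_conc, kd)
  idx <- match(binders$residue_number, base_peaks$residue_number)
  points <- with_seed(seed, lapply(seq_along(ratios), function(k) {
    h <- base_peaks$h_ppm
    n <- base_peaks$n_ppm
    h[idx] <- h[idx] + fb[k] * binders$d_h_max
    n[idx] <- n[idx] + fb[k] * binders$d_n_max
    if (noise_ppm > 0) {
      h <- h + stats::rnorm(length(h), 0, noise_ppm)
      n <- n + stats::rnorm(length(n), 0, N_SCALE * noise_ppm)
    }
    suppressWarnings(
      peak_list(base_peaks$residue_number, base_peaks$residue_type, h, n,
                height = base_peaks$height))
  }))
  out <- titration_series(points, ratios, protein_conc = protein_conc,
                          ligand_id = "synthetic")
  attr(out, "truth") <- list(binders = binders, kd = kd,
                             protein_conc = protein_conc,
                             fraction_bound = fb)
  out
}

#' Model-free 15N relaxation rates (spectral-density oracle)
#'
#' Standard 15N dipolar + CSA expressions for R1, R2 and the steady-state
#' {1H}15N NOE under the Lipari-Szabo spectral density
#' `J(w) = (2/5) [S^2 tau_c / (1 + (w tau_c)^2) + (1 - S^2) tau /
#' (1 + (w tau)^2)]` with `1/tau = 1/tau_c + 1/tau_e`, for an isotropic
#' tumbler.  An exchange contribution `rex` adds to R2 only.  This routine
#' is independent of the R2/R1 correlation-time estimator and serves as its
#' physical oracle.
#'
#' @param tau_c_ns Overall rotational correlation time (ns), > 0.
#' @param field_proton_mhz Proton Larmor frequency (MHz).
#' @param s2 Order parameter in [0, 1] (1 = rigid).
#' @param tau_e_ps Internal correlation time (ps); ignored when `s2 = 1`.
#' @param rex Exchange contribution to R2 (1/s).
#' @param r_nh_angstrom N-H bond length (default 1.02 A).
#' @param delta_sigma_ppm 15N CSA (default -160 ppm).
#' @return A list: `r1`, `r2` (1/s), `noe` (ratio), `nu_n_hz`.
#' @export
simulate_relaxation_rates <- function(tau_c_ns, field_proton_mhz,
                                      s2 = 1, tau_e_ps = 0, rex = 0,
                                      r_nh_angstrom = 1.02,
                                      delta_sigma_ppm = -160) {
  if (!is.numeric(tau_c_ns) || tau_c_ns <= 0)
    nd_stop("nmrdomain_value_error", "tau_c must be > 0")
  if (s2 < 0 || s2 > 1)
    nd_stop("nmrdomain_value_error", "s2 must lie in [0, 1]")
  tau_c <- tau_c_ns * 1e-9
  tau_e <- tau_e_ps * 1e-12
  w_h <- 2 * pi * field_proton_mhz * 1e6
  w_n <- w_h * abs(.GAMMA_N) / .GAMMA_H
  d <- .MU0_OVER_4PI * .HBAR * .GAMMA_H * abs(.GAMMA_N) /
    (r_nh_angstrom * 1e-10)^3
  c_csa <- w_n * delta_sigma_ppm * 1e-6 / sqrt(3)
  jw <- function(w) {
    tau <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else tau_c
    0.4 * (s2 * tau_c / (1 + (w * tau_c)^2) +
           (1 - s2) * tau / (1 + (w * tau)^2))
  }
  r1 <- (d^2 / 4) * (jw(w_h - w_n) + 3 * jw(w_n) + 6 * jw(w_h + w_n)) +
    c_csa^2 * jw(w_n)
  r2 <- (d^2 / 8) * (4 * jw(0) + jw(w_h - w_n) + 3 * jw(w_n) +
                     6 * jw(w_h) + 6 * jw(w_h + w_n)) +
    (c_csa^2 / 6) * (4 * jw(0) + 3 * jw(w_n)) + rex
  # NOE needs the signed 15N gyromagnetic ratio
  noe <- 1 + (d^2 / 4) * (.GAMMA_H / .GAMMA_N) *
    (6 * jw(w_h + w_n) - jw(w_h - w_n)) / r1
  list(r1 = r1, r2 = r2, noe = noe,
       nu_n_hz = w_n / (2 * pi))
}

#' Delay-list presets for relaxation experiments
#'
#' Named presets covering commonly used T1, T2 and T1rho delay series for
#' small domains at 600-700 MHz (two T1/T2 variants spanning slower- and
#' faster-relaxing samples).
#'
#' @param preset One of `"paper_T1"`, `"paper_T2"`, `"paper_T1rho"`,
#'   `"paper_T1_rrm"`, `"paper_T2_rrm"`.
#' @return Numeric vector of delays in ms.
#' @export
relaxation_delays <- function(preset = c("paper_T1", "paper_T2",
                                         "paper_T1rho", "paper_T1_rrm",
                                         "paper_T2_rrm")) {
  switch(match.arg(preset),
    paper_T1 = c(20, 40, 80, 100, 200, 400, 600, 1000, 1400),
    paper_T2 = c(16.96, 33.92, 67.84, 101.76, 135.68, 169.6, 203.52,
                 271.36, 339.2),
    paper_T1rho = c(4, 8, 12, 24, 48, 72, 96, 120, 144),
    paper_T1_rrm = c(10, 50, 150, 250, 350, 500, 750, 1500, 2500),
    paper_T2_rrm = c(33.92, 50.88, 67.84, 84.8, 101.76, 118.72, 135.68,
                     152.64, 169.6, 203.52, 271.36))
}

#' Generate mono-exponential relaxation decays
#'
#' `I(t) = i0 * exp(-R t)` per residue, with multiplicative Gaussian noise
#' of relative SD `noise_frac`.
#'
#' @param rates Per-residue rates in 1/s; names (or positions 1..n) become
#'   residue numbers.
#' @param delays Delay list in ms (>= 4 values); see [relaxation_delays()].
#' @param noise_frac Relative noise SD (0 = exact exponential).
#' @param seed RNG seed.
#' @param experiment,field_proton_mhz Metadata for the resulting series.
#' @param i0 Intensity at zero delay.
#' @return A [relaxation_series()] with attribute `truth` (the input
#'   rates).
#' @export
gen_relaxation_decays <- function(rates, delays = relaxation_delays("paper_T1"),
                                  noise_frac = 0, seed = NULL,
                                  experiment = "T1", field_proton_mhz = 600,
                                  i0 = 100) {
  if (length(delays) == 0L)
    nd_stop("nmrdomain_value_error", "empty delay list")
  if (length(delays) < 4L)
    nd_stop("nmrdomain_value_error", "need >= 4 delays")
  if (any(rates <= 0))
    nd_stop("nmrdomain_value_error", "rates must be > 0")
  res <- if (!is.null(names(rates))) as.integer(names(rates))
    else seq_along(rates)
  df <- with_seed(seed, {
    rows <- lapply(seq_along(rates), function(i) {
      ideal <- i0 * exp(-rates[i] * delays / 1000)
      noisy <- if (noise_frac > 0)
        ideal * (1 + stats::rnorm(length(delays), 0, noise_frac)) else ideal
      data.frame(residue = res[i], delay_ms = delays, intensity = noisy)
    })
    do.call(rbind, rows)
  })
  out <- relaxation_series(df, experiment = experiment,
                           field_proton_mhz = field_proton_mhz)
  attr(out, "truth") <- list(rates = stats::setNames(unname(rates), res))
  out
}

#' Generate a synthetic chemical-shift table with planted secondary structure
#'
#' Random-coil Ca/Cb values plus helix/strand offsets inside the planted
#' elements plus seeded Gaussian noise.  The default offsets
#' (helix +2.8/-0.4 ppm on Ca/Cb, strand -1.5/+2.0 ppm) lie within the
#' empirically observed ranges for well-formed elements.
#'
#' @param sequence One-letter sequence of the simulated chain.
#' @param start Residue number of the first sequence position.
#' @param sse An `sse_annotation`-style data frame (`kind`, `start`, `end`)
#'   of planted, non-overlapping elements.
#' @param rc Random-coil table.
#' @param noise_ppm Gaussian noise SD added independently to Ca and Cb.
#' @param seed RNG seed.
#' @param helix_offset,strand_offset Length-2 vectors `c(ca, cb)` in ppm.
#' @return A [shift_table()] of CA/CB shifts with attribute `truth` (the
#'   planted annotation).
#' @export
gen_scs_dataset <- function(sequence, start = 1L, sse = NULL,
                            rc = random_coil_table(), noise_ppm = 0,
                            seed = NULL,
                            helix_offset = c(2.8, -0.4),
                            strand_offset = c(-1.5, 2.0)) {
  chars <- seq_chars(sequence)
  check_residue_types(chars, "sequence")
  res <- seq.int(start, start + length(chars) - 1L)
  if (is.null(sse))
    sse <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0))
  if (nrow(sse) > 0L) {
    if (any(sse$start < start | sse$end > max(res) | sse$start > sse$end))
      nd_stop("nmrdomain_value_error", "planted elements outside sequence")
    pos <- unlist(mapply(seq.int, sse$start, sse$end, SIMPLIFY = FALSE))
    if (anyDuplicated(pos))
      nd_stop("nmrdomain_value_error", "planted elements overlap")
  }
  idx <- match(chars, rc$residue_type)
  ca <- rc$coil_ca[idx]
  cb <- rc$coil_cb[idx]
  for (i in seq_len(nrow(sse))) {
    span <- res >= sse$start[i] & res <= sse$end[i]
    off <- if (sse$kind[i] == "helix") helix_offset else strand_offset
    ca[span] <- ca[span] + off[1]
    cb[span] <- cb[span] + off[2]
  }
  out <- with_seed(seed, {
    if (noise_ppm > 0) {
      ca <- ca + stats::rnorm(length(ca), 0, noise_ppm)
      cb <- cb + stats::rnorm(length(cb), 0, noise_ppm)
    }
    has_cb <- !is.na(cb)
    shift_table(c(res, res[has_cb]),
                c(chars, chars[has_cb]),
                c(rep("CA", length(res)), rep("CB", sum(has_cb))),
                c(ca, cb[has_cb]))
  })
  attr(out, "truth") <- sse
  out
}

#' Generate a synthetic hetNOE profile with a rigid core
#'
#' A plateau at `plateau` inside the core, decaying linearly over
#' `edge_width` residues outside the core boundaries to `terminal` at the
#' termini, plus seeded Gaussian noise.
#'
#' @param residues Residue numbers of the profile.
#' @param core `c(start, end)` of the planted rigid core.
#' @param plateau hetNOE value inside the core (default 0.8).
#' @param terminal hetNOE value at the flexible termini (default 0.2).
#' @param noise Gaussian noise SD (default 0).
#' @param seed RNG seed.
#' @param edge_width Residues over which the plateau decays (default 3).
#' @return A `hetnoe_profile` with attribute `truth` (the planted core).
#' @export
gen_hetnoe_dataset <- function(residues = 18:70, core = c(30, 67),
                               plateau = 0.8, terminal = 0.2, noise = 0,
                               seed = NULL, edge_width = 3L) {
  dist_out <- pmax(core[1] - residues, residues - core[2], 0)
  value <- plateau - (plateau - terminal) * pmin(dist_out, edge_width) /
    edge_width
  out <- with_seed(seed, {
    if (noise > 0) value <- value + stats::rnorm(length(value), 0, noise)
    hetnoe_profile(residues, value, error = noise)
  })
  attr(out, "truth") <- list(core = core, plateau = plateau,
                             terminal = terminal)
  out
}

# Typical low-molecular-weight gel-filtration standard set (kDa).
DEFAULT_SEC_STANDARDS <- data.frame(
  name = c("conalbumin", "ovalbumin", "carbonic_anhydrase",
           "ribonuclease_a", "aprotinin"),
  mw_kda = c(75, 44, 29, 13.7, 6.5),
  stringsAsFactors = FALSE)

#' Generate a synthetic SEC calibration run
#'
#' Elution volumes are produced from a known ground-truth line
#' `Kav = slope * log10(MW) + intercept` on an analytical column
#' (defaults resemble a 24-mL analytical gel-filtration column), plus
#' optional Gaussian volume noise; samples elute according to their
#' apparent MW on the same line.
#'
#' @param standards Data frame `name`, `mw_kda` (defaults to a typical
#'   five-protein low-MW kit).
#' @param v0,vc Void and total column volumes (mL).
#' @param slope,intercept Ground-truth calibration line.
#' @param samples Optional named numeric vector of sample apparent MWs
#'   (kDa).
#' @param noise_ml Gaussian SD on elution volumes (mL).
#' @param seed RNG seed.
#' @return A list: `standards` (with `ve_ml`), `samples` (with `ve_ml`, or
#'   `NULL`), `v0`, `vc`, `truth` (the line).
#' @export
gen_sec_run <- function(standards = DEFAULT_SEC_STANDARDS, v0 = 8.0,
                        vc = 23.6, slope = -0.35, intercept = 0.9,
                        samples = NULL, noise_ml = 0, seed = NULL) {
  ve_of <- function(mw) {
    kav <- slope * log10(mw) + intercept
    v0 + kav * (vc - v0)
  }
  with_seed(seed, {
    standards$ve_ml <- ve_of(standards$mw_kda) +
      if (noise_ml > 0) stats::rnorm(nrow(standards), 0, noise_ml) else 0
    smp <- NULL
    if (!is.null(samples)) {
      smp <- data.frame(name = names(samples) %||%
                          paste0("sample", seq_along(samples)),
                        apparent_mw_kda = unname(samples),
                        ve_ml = ve_of(unname(samples)) +
                          if (noise_ml > 0)
                            stats::rnorm(length(samples), 0, noise_ml)
                          else 0,
                        stringsAsFactors = FALSE)
    }
    list(standards = standards, samples = smp, v0 = v0, vc = vc,
         truth = list(slope = slope, intercept = intercept))
  })
}
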