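#' Nearest-neighbor free-energy parameters for hairpin folding
#'
#' Constructs the thermodynamic parameter set used by [min_hairpin()],
#' [hairpin_energy()] and [enumerate_hairpins()]. The defaults are a
#' Turner-2004-style nearest-neighbor set at 37 degrees C: Watson-Crick and
#' G.U wobble stacking free energies, hairpin-loop initiation penalties for
#' loop sizes 3..30, bulge initiation for 1..6 unpaired nt, internal-loop
#' initiation for total sizes 2..6, and a terminal A-U/G-U closing penalty.
#' Loop sizes beyond the tabulated range are extrapolated with the
#' Jacobson-Stockmayer form
#' \deqn{\Delta G(n) = \Delta G(n_{max}) + 1.75 \, R T \ln(n / n_{max})}
#' with R = 1.987e-3 kcal/(mol K) and T = 310.15 K.
#'
#' The model is deliberately reduced relative to full secondary-structure
#' folding engines: no terminal-mismatch or dangling-end terms, no special
#' small internal-loop tables, and a single-hairpin search space. Absolute
#' free energies therefore differ somewhat from Mfold/ViennaRNA values and
#' should be read as a consistent internal scale, not as literature-exact
#' per-structure energies.
#'
#' All energies are in kcal/mol. Internally every energy is handled in
#' integer hundredths of a kcal/mol ("cents") so that sums are exact and
#' platform-independent; `dG` values exposed to the user are cents / 100.
#'
#' @param scale numeric multiplier applied to every energy term (used in
#'   tests of linearity; default 1).
#' @return An object of class `energy_params`: a list with elements
#'   `stack_dG` (6x6 matrix, rows = outer pair, cols = inner pair, pair
#'   codes "AU","UA","CG","GC","GU","UG"), `hairpin_init` (named vector,
#'   sizes 3..30), `bulge_init` (sizes 1..6), `internal_init` (total sizes
#'   2..6), `terminal_AU_penalty`, `R`, `T`, `js_coef`, and `version_tag`.
#' @examples
#' p <- energy_params()
#' p$stack_dG["GC", "GC"]   # 5'-GG-3' / 3'-CC-5' stack
#' @export
energy_params <- function(scale = 1) {
  pair_codes <- c("AU", "UA", "CG", "GC", "GU", "UG")
  # Stacking free energies, kcal/mol at 37 C. Entry [p1, p2] is the stack
  # formed by outer pair p1 = (i, j) on inner pair p2 = (i+1, j-1), both
  # read (5' base, 3' base). Watson-Crick values follow Xia et al. (1998),
  # wobble values the Turner 2004 compilation.
  S <- matrix(NA_real_, 6, 6, dimnames = list(pair_codes, pair_codes))
  S["CG", ] <- c(AU = -2.10, UA = -2.10, CG = -3.30, GC = -2.40, GU = -1.40, UG = -2.10)
  S["GC", ] <- c(AU = -2.40, UA = -2.20, CG = -3.40, GC = -3.30, GU = -1.50, UG = -2.50)
  S["GU", ] <- c(AU = -1.30, UA = -1.40, CG = -2.50, GC = -2.10, GU = -0.50, UG =  1.30)
  S["UG", ] <- c(AU = -1.00, UA = -0.60, CG = -1.50, GC = -1.40, GU =  0.30, UG = -0.50)
  S["AU", ] <- c(AU = -0.90, UA = -1.10, CG = -2.20, GC = -2.10, GU = -0.60, UG = -1.40)
  S["UA", ] <- c(AU = -1.30, UA = -0.90, CG = -2.40, GC = -2.10, GU = -1.00, UG = -1.30)

  hairpin_init <- c(
    5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40, 6.50,
    6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10,
    7.20, 7.20, 7.30, 7.30, 7.40, 7.40, 7.50, 7.50,
    7.50, 7.60, 7.60, 7.70
  )
  names(hairpin_init) <- as.character(3:30)

  bulge_init <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40)
  names(bulge_init) <- as.character(1:6)

  internal_init <- c(1.00, 1.00, 1.10, 2.00, 2.00)
  names(internal_init) <- as.character(2:6)

  p <- list(
    stack_dG = S * scale,
    hairpin_init = hairpin_init * scale,
    bulge_init = bulge_init * scale,
    internal_init = internal_init * scale,
    terminal_AU_penalty = 0.50 * scale,
    R = 1.987e-3,
    T = 310.15,
    js_coef = 1.75,
    version_tag = "nn37-turner2004-style-1.0"
  )
  class(p) <- "energy_params"
  validate_energy_params(p)
  p
}

validate_energy_params <- function(p) {
  stopifnot(inherits(p, "energy_params"))
  wc <- c("AU", "UA", "CG", "GC")
  if (!all(p$stack_dG[wc, wc] < 0))
    stop("invalid energy_params: some Watson-Crick stack is non-negative")
  if (!all(p$hairpin_init > 0) || !all(p$bulge_init > 0) ||
      !all(p$internal_init > 0))
    stop("invalid energy_params: loop initiation penalties must be positive")
  if (!identical(names(p$hairpin_init), as.character(3:30)) ||
      !identical(names(p$bulge_init), as.character(1:6)) ||
      !identical(names(p$internal_init), as.character(2:6)))
    stop("invalid energy_params: incomplete loop tables")
  invisible(p)
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Nearest-neighbor hairpin energy parameters (", x$version_tag, ")\n",
      sep = "")
  cat("  stacks: 6x6 over {AU,UA,CG,GC,GU,UG}; terminal AU/GU penalty ",
      x$terminal_AU_penalty, " kcal/mol\n", sep = "")
  cat("  hairpin init 3..30, bulge 1..6, internal 2..6;",
      "Jacobson-Stockmayer extrapolation beyond\n")
  invisible(x)
}

# --- integer "cents" view used by the folding engine and the oracle -------

# Convert a parameter set to integer hundredths of kcal/mol. Rounding
# happens once, here, so the C++ engine and the R oracle see identical
# integers and energy sums are exact.
params_cents <- function(p) {
  validate_energy_params(p)
  list(
    stack = round(p$stack_dG * 100),
    hairpin = round(p$hairpin_init * 100),
    bulge = round(p$bulge_init * 100),
    internal = round(p$internal_init * 100),
    term_au = round(p$terminal_AU_penalty * 100),
    js_rt = p$js_coef * p$R * p$T   # kcal/mol multiplier of ln(n/nmax)
  )
}

# Loop penalty in cents for a loop of class "hairpin" | "bulge" | "internal"
# and total unpaired size n, with Jacobson-Stockmayer extrapolation past the
# table end (rounded to a whole cent so arithmetic stays integral).
loop_penalty_cents <- function(kind, n, pc) {
  tab <- switch(kind, hairpin = pc$hairpin, bulge = pc$bulge,
                internal = pc$internal)
  sizes <- as.integer(names(tab))
  nmax <- max(sizes)
  if (n < min(sizes)) stop("loop size ", n, " below table for ", kind)
  if (n <= nmax) return(unname(tab[as.character(n)]))
  unname(tab[as.character(nmax)]) +
    round(100 * pc$js_rt * log(n / nmax))
}
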