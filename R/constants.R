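# Physical constants (CODATA 2018) in SI units, plus unit helpers.
.const <- list(
  hbar  = 1.054571817e-34,   # J s
  k_B   = 1.380649e-23,      # J / K
  c_cm  = 2.99792458e10,     # speed of light, cm / s
  amu   = 1.66053906660e-27, # kg
  m2_to_A2 = 1e20            # m^2 -> Angstrom^2
)

# Atomic numbers and masses (most abundant / standard atomic weight) for the
# elements this package routinely meets in organic and small-molecule crystals.
.elements <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl",
             "K", "Ca", "Fe", "Br", "I"),
  z      = c(1, 5, 6, 7, 8, 9, 11, 12, 14, 15, 16, 17, 19, 20, 26, 35, 53),
  mass   = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
             28.086, 30.974, 32.06, 35.45, 39.098, 40.078, 55.845, 79.904,
             126.904),
  # Covalent radii in Angstrom (Cordero et al. 2008 single-bond values)
  r_cov  = c(0.31, 0.84, 0.77, 0.71, 0.66, 0.57, 1.66, 1.41, 1.11, 1.07, 1.05,
             1.02, 2.03, 1.76, 1.32, 1.20, 1.39),
  stringsAsFactors = FALSE
)

element_info <- function(symbol, field) {
  sym <- normalize_element(symbol)
  i <- match(sym, .elements$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ", paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .elements[[field]][i]
}

atomic_number <- function(symbol) element_info(symbol, "z")
atomic_mass   <- function(symbol) element_info(symbol, "mass")
covalent_radius <- function(symbol) element_info(symbol, "r_cov")

normalize_element <- function(symbol) {
  s <- tolower(trimws(symbol))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}
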