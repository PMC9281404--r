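#' Unit conversions for membrane mechanics
#'
#' The package works in the units molecular-dynamics engines print:
#' pressures in bar, lengths in nm, tensions in bar nm or mN/m, energies
#' in kJ/mol. The conversions are exact:
#' 1 bar nm = 0.1 mN/m, and 1 mN/m nm^2 = 1e-21 J = 0.602214076 kJ/mol
#' (Avogadro scaling), so a tension expressed per area in kJ/mol/nm^2 is
#' the mN/m value times the same constant.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' bar_nm_to_mN_m(1000)      # 100 mN/m
#' mN_m_nm2_to_kJ_mol(70)    # ~42.2 kJ/mol
#' @name units
NULL

# N_A * 1e-21 J in kJ/mol; shared by tension*area -> energy and
# tension -> energy/area conversions
.KJ_PER_MNM_NM2 <- 0.602214076

#' @rdname units
#' @export
bar_nm_to_mN_m <- function(x) x * 0.1

#' @rdname units
#' @export
mN_m_to_bar_nm <- function(x) x * 10

#' @rdname units
#' @export
mN_m_nm2_to_kJ_mol <- function(x) x * .KJ_PER_MNM_NM2

#' @rdname units
#' @export
kJ_mol_to_mN_m_nm2 <- function(x) x / .KJ_PER_MNM_NM2

#' @rdname units
#' @export
mN_m_to_kJ_mol_nm2 <- function(x) x * .KJ_PER_MNM_NM2

#' @rdname units
#' @export
kJ_mol_nm2_to_mN_m <- function(x) x / .KJ_PER_MNM_NM2

#' Parse a human-readable duration into picoseconds
#'
#' Accepts plain numbers (already ps) or strings with an fs/ps/ns/us/ms
#' suffix, e.g. `"50ns"` -> 50000 ps. Used by the command-line interface.
#'
#' @param x number or string such as `"100ns"`.
#' @return duration in ps.
#' @export
parse_duration_ps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(tolower(as.character(x)))
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*(fs|ps|ns|us|ms)?$", x))[[1]]
  if (length(m) == 0L || m[2] == "")
    stop("cannot parse duration: ", sQuote(x), call. = FALSE)
  val <- as.numeric(m[2])
  if (is.na(val)) stop("cannot parse duration: ", sQuote(x), call. = FALSE)
  mult <- switch(ifelse(m[3] == "", "ps", m[3]),
                 fs = 1e-3, ps = 1, ns = 1e3, us = 1e6, ms = 1e9)
  val * mult
}
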