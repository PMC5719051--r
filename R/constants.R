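#' Elements and plant groups used throughout the package
#'
#' `resorb_elements()` returns the six leaf elements analysed
#' (concentrations in mg g^-1); `resorb_groups()` returns the four plant
#' groups: euhalophytes (Eu), secretohalophytes (Se), pseudohalophytes
#' (Ps) and glycophytes (Gl).
#'
#' @return Character vector.
#' @export
resorb_elements <- function() c("N", "P", "K", "Na", "Ca", "Mg")

#' @rdname resorb_elements
#' @export
resorb_groups <- function() c("Eu", "Se", "Ps", "Gl")

# Published group-level means of element concentration (mg g^-1) in green
# and senesced leaves, used as generator defaults.  Rows = plant group,
# columns = element.
.group_mean_green <- matrix(
  c(28.8, 2.84, 22.2, 53.5, 11.6, 19.0,
    21.2, 2.09, 8.19, 24.9, 12.6, 23.9,
    22.8, 2.15, 18.8, 3.19, 7.14, 12.5,
    28.8, 3.31, 22.7, 13.2, 13.1, 11.6),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("Eu", "Se", "Ps", "Gl"),
                  c("N", "P", "K", "Na", "Ca", "Mg"))
)

.group_mean_senesced <- matrix(
  c(14.4, 1.40, 12.6, 70.2, 12.4, 20.1,
    12.7, 1.02, 6.55, 20.3, 12.1, 20.5,
    14.0, 1.25, 10.6, 4.54, 9.43, 15.7,
    18.7, 1.71, 13.3, 20.0, 17.5, 13.8),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("Eu", "Se", "Ps", "Gl"),
                  c("N", "P", "K", "Na", "Ca", "Mg"))
)

# Group sample sizes (number of species) in the emulated study design.
.group_n_species <- c(Eu = 10, Se = 5, Ps = 11, Gl = 10)

#' Reference group-level leaf element concentrations
#'
#' Group-by-element matrices of mean element concentration (mg g^-1) in
#' green and senesced leaves for the four plant groups.  These are the
#' defaults the synthetic-data generator emulates.
#'
#' @param status `"green"` or `"senesced"`.
#' @return A 4 x 6 numeric matrix (groups x elements).
#' @export
#' @examples
#' group_mean_concentrations("green")["Eu", "Na"] # 53.5 mg/g
group_mean_concentrations <- function(status = c("green", "senesced")) {
  status <- match.arg(status)
  if (status == "green") .group_mean_green else .group_mean_senesced
}

# Derive a child seed from a user seed; keeps results within 32-bit
# integer range so set.seed() accepts it.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(k)) %% 2147483587)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL leaves the RNG alone.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                        .rng_normal_kind = "Inversion",
                        .rng_sample_kind = "Rejection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
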