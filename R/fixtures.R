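# Gene-expression fixture generator: per-phenotype synthesis levels for a
# ligand/receptor isoform pair, optionally perturbed by multiplicative
# noise. The packaged TGFB2/TGFBR3 pair carries the tabulated values used
# by the coupled cellular-tissue runs; "synthetic" fixtures emulate the
# phenotype-dependent expression profiles a microarray reanalysis would
# produce, without requiring any download.

.isoform_fixtures <- list(
  "TGFB2/TGFBR3" = list(beta_sM = c(1.853, 1.724, 1.614, 1.669),
                        R_sM    = c(7.47, 6.713, 5.017, 4.128))
)

#' Generate a per-phenotype expression fixture
#'
#' @param label Isoform pair label (`"TGFB2/TGFBR3"`) or `"synthetic"`.
#' @param noise Multiplicative noise scale (log-normal sdlog); 0 returns
#'   the base vectors exactly, independent of the seed.
#' @param seed RNG seed (fixtures are reproducible given
#'   `(label, noise, seed)`).
#' @param Phi Maximum phenotype index (vectors have length `Phi + 1`).
#' @return List of class `expression_fixture`: `label`, `beta_sM`, `R_sM`,
#'   `noise`, `seed`. Vectors are non-negative.
#' @export
#' @examples
#' generate_expression_fixture("TGFB2/TGFBR3", 0)$beta_sM
generate_expression_fixture <- function(label = "TGFB2/TGFBR3", noise = 0,
                                        seed = 1L, Phi = 3L) {
  stopifnot(noise >= 0)
  if (label %in% names(.isoform_fixtures)) {
    base <- .isoform_fixtures[[label]]
    if (length(base$beta_sM) != Phi + 1L) {
      stop(sprintf("fixture '%s' is defined for Phi = %d", label,
                   length(base$beta_sM) - 1L))
    }
  } else if (identical(label, "synthetic")) {
    base <- .isoform_fixtures[["TGFB2/TGFBR3"]]
  } else {
    stop(sprintf("unknown isoform fixture label '%s'", label))
  }
  beta_sM <- base$beta_sM
  R_sM <- base$R_sM
  if (noise > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    beta_sM <- beta_sM * rlnorm(length(beta_sM), 0, noise)
    R_sM <- R_sM * rlnorm(length(R_sM), 0, noise)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(label = label, beta_sM = beta_sM, R_sM = R_sM,
                 noise = noise, seed = seed),
            class = "expression_fixture")
}
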