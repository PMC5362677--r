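# Built-in synthetic study designs.  The presets span the package's
# reference error studies: one- to three-dimensional Gaussian class pairs,
# imbalanced pattern sets, a bimodal/trimodal mixture design, and the
# counting baseline.  Names follow the package's numbered study tables.

GAUSS_M_GRID <- c(10L, 20L, 50L, 100L, 200L, 500L, 1000L)

#' Built-in experiment presets
#'
#' Returns a ready-to-run [experiment_config()] for one of the package's
#' numbered synthetic study designs:
#' \describe{
#'   \item{`table1`}{1-d, N(0,1) vs N(2,1), interval lengths 0, 0.1, 0.25,
#'     0.5, 1, 2, 5 (length 0 = crisp PNN).}
#'   \item{`table2`}{2-d, N((0,0), I) vs N((2,0), I), lengths 0.1, 0.5, 2.}
#'   \item{`table3`}{3-d, N((0,0,0), I) vs N((2,0,0), I), same lengths.}
#'   \item{`table4`}{as `table1` restricted to lengths 0.1, 0.5, 2
#'     (equinumerous reference for the imbalance studies).}
#'   \item{`table5`}{1-d with imbalanced patterns, m1 = 2 m2.}
#'   \item{`table6`}{1-d with imbalanced patterns, m1 = 10 m2.}
#'   \item{`table7`}{2-d multimodal: class 1 a 1/3-1/3-1/3 mixture of
#'     N((0,0), I), N((2,0), I), N((4,0), I); class 2 a 1/2-1/2 mixture of
#'     N((1, sqrt(3)), I), N((3, sqrt(3)), I) - component means at the
#'     vertices of an inverted W.}
#'   \item{`table14`}{the counting-baseline design on the 1-d Gaussian pair
#'     (run it with [run_counting_experiment()]), m up to 500.}
#' }
#' All presets use 1000 test items per class and 100 repetitions by
#' default.  In the imbalanced designs (`table5`, `table6`) the pattern-set
#' sizes are a sampling artefact while the test mix stays 50/50, so these
#' presets compare the normalized class densities (`prior = "uniform"`);
#' all equinumerous designs keep the frequency prior, for which the two
#' rules coincide.
#'
#' @param name preset name (see above).
#' @param m optional subset/override of the pattern-size grid: a vector of
#'   per-class-2 sizes for the imbalanced designs, otherwise of per-class
#'   sizes.
#' @param lengths optional override of the interval lengths.
#' @param repetitions,test_per_class,seed,c optional overrides of
#'   [experiment_config()] fields.
#' @return an [experiment_config()].
#' @export
experiment_preset <- function(name, m = NULL, lengths = NULL,
                              repetitions = 100, test_per_class = 1000,
                              seed = 1, c = 0.5) {
  gauss_pair <- function(dim) {
    e2 <- c(2, rep(0, dim - 1))
    list(class1 = class_spec(rep(0, dim)), class2 = class_spec(e2))
  }
  spec <- switch(name,
    table1 = list(classes = gauss_pair(1),
                  lengths = c(0, 0.1, 0.25, 0.5, 1, 2, 5),
                  m_grid = as.list(GAUSS_M_GRID), prior = "frequency"),
    table2 = list(classes = gauss_pair(2), lengths = c(0.1, 0.5, 2),
                  m_grid = as.list(GAUSS_M_GRID), prior = "frequency"),
    table3 = list(classes = gauss_pair(3), lengths = c(0.1, 0.5, 2),
                  m_grid = as.list(GAUSS_M_GRID), prior = "frequency"),
    table4 = list(classes = gauss_pair(1), lengths = c(0.1, 0.5, 2),
                  m_grid = as.list(GAUSS_M_GRID), prior = "frequency"),
    table5 = list(classes = gauss_pair(1), lengths = c(0.1, 0.5, 2),
                  m_grid = lapply(GAUSS_M_GRID, function(m2) c(2L * m2, m2)),
                  prior = "uniform"),
    table6 = list(classes = gauss_pair(1), lengths = c(0.1, 0.5, 2),
                  m_grid = lapply(GAUSS_M_GRID, function(m2) c(10L * m2, m2)),
                  prior = "uniform"),
    table7 = list(classes = list(
                    class1 = class_spec(rbind(c(0, 0), c(2, 0), c(4, 0)),
                                        rep(1 / 3, 3)),
                    class2 = class_spec(rbind(c(1, sqrt(3)), c(3, sqrt(3))),
                                        c(0.5, 0.5))),
                  lengths = c(0.1, 0.5, 2),
                  m_grid = as.list(GAUSS_M_GRID), prior = "frequency"),
    table14 = list(classes = gauss_pair(1), lengths = c(0.1, 0.5, 2),
                   m_grid = as.list(c(10L, 20L, 50L, 100L, 200L, 500L)),
                   prior = "frequency"),
    abort_invalid_argument(sprintf(
      "unknown preset '%s' (available: table1-table7, table14)", name))
  )
  if (!is.null(m)) {
    m <- as.integer(m)
    spec$m_grid <- switch(name,
      table5 = lapply(m, function(m2) c(2L * m2, m2)),
      table6 = lapply(m, function(m2) c(10L * m2, m2)),
      as.list(m)
    )
  }
  if (!is.null(lengths)) spec$lengths <- lengths
  experiment_config(
    class_specs = spec$classes,
    m_grid = spec$m_grid,
    interval_lengths = spec$lengths,
    test_per_class = test_per_class,
    repetitions = repetitions,
    seed = seed, c = c, prior = spec$prior
  )
}
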