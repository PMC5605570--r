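#' Generate the synthetic cohort design
#'
#' Lays out animals in batches of cages (3 mice per cage), randomly assigns
#' half the cages of each batch to the enriched (E) and half to the control
#' (C) condition, and allocates exactly one mouse per cage to each assay arm
#' (IHC, PCR, ELISA). Enriched mice receive a fur-mark pattern so individuals
#' can be told apart on video. With the default design this yields 96 animals
#' and 16 IHC animals per treatment.
#'
#' @param config a [generator_config()].
#' @return a data.frame with one row per animal: \code{animal_id},
#'   \code{batch}, \code{cage_id}, \code{treatment} ("E"/"C"), \code{arm}
#'   ("IHC"/"PCR"/"ELISA"), \code{mark_pattern}, and \code{proc_order} (the
#'   alternating E/C processing order at collection).
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 1))
#' table(cohort$treatment, cohort$arm)
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(sub_seed(config, "cohort"))
  cages_per_batch <- config$animals_per_batch / 3L
  arms <- c("IHC", "PCR", "ELISA")
  marks <- c("none", "one_stripe", "two_stripes")
  rows <- vector("list", config$n_batches * cages_per_batch)
  k <- 0L
  for (b in seq_len(config$n_batches)) {
    trt <- sample(rep(c("E", "C"), each = cages_per_batch / 2L))
    for (cg in seq_len(cages_per_batch)) {
      k <- k + 1L
      cage_id <- sprintf("b%d_c%d", b, cg)
      arm <- sample(arms)          # one animal per cage in each arm
      mark <- if (trt[cg] == "E") sample(marks) else rep("none", 3L)
      rows[[k]] <- data.frame(
        animal_id = sprintf("%s_m%d", cage_id, 1:3),
        batch = b,
        cage_id = cage_id,
        treatment = trt[cg],
        arm = arm,
        mark_pattern = mark,
        stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, rows)
  # alternate E/C at collection so order effects are testable downstream
  proc <- integer(nrow(cohort))
  e_idx <- which(cohort$treatment == "E")
  c_idx <- which(cohort$treatment == "C")
  n <- min(length(e_idx), length(c_idx))
  proc[e_idx[seq_len(n)]] <- 2 * seq_len(n) - 1
  proc[c_idx[seq_len(n)]] <- 2 * seq_len(n)
  cohort$proc_order <- proc
  rownames(cohort) <- NULL
  cohort
}
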