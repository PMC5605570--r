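# Stage functions compose generator -> quantification per modality; the
# orchestrator chains them and runs the repeated-measures analyses.

#' Image-quantification study: DCX normalized area per IHC animal
#'
#' Generates DCX section frames for every IHC-arm animal of the cohort and
#' runs the full threshold-area-normalize-aggregate chain. Ground-truth
#' stained fractions (pooled over frames like the estimate) ride along.
#'
#' @param cohort [generate_cohort()] output.
#' @param config a [generator_config()].
#' @return data.frame: one row per animal x region with \code{normalized},
#'   its components, \code{treatment} and \code{true_fraction}.
#' @export
dcx_ihc_study <- function(cohort, config) {
  ihc <- cohort[cohort$arm == "IHC", ]
  rows <- lapply(seq_len(nrow(ihc)), function(i) {
    an <- ihc[i, ]
    frames <- generate_section_images(an, config)
    q <- aggregate_dcx(frames)
    truth <- vapply(split(frames, vapply(frames, `[[`, "", "region")),
                    function(fr) {
                      pos <- sum(vapply(fr, function(f) f$truth$positive_px, 1))
                      gcl <- sum(vapply(fr, function(f) f$truth$gcl_px, 1))
                      pos / gcl
                    }, numeric(1))
    q$true_fraction <- truth[q$region]
    q$treatment <- an$treatment
    q$cage_id <- an$cage_id
    q
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Densitometry study: corrected BDNF ROD per IHC animal
#'
#' @inheritParams dcx_ihc_study
#' @return data.frame of per-animal, per-region, per-site corrected ROD with
#'   treatment and generator truth.
#' @export
bdnf_rod_study <- function(cohort, config) {
  ihc <- cohort[cohort$arm == "IHC", ]
  rows <- lapply(seq_len(nrow(ihc)), function(i) {
    an <- ihc[i, ]
    frames <- generate_bdnf_images(an, config)
    rod <- background_correct(frames)
    truth <- lapply(frames, function(f) f$truth$site_od)
    regions <- vapply(frames, `[[`, "", "region")
    rod$true_od <- mapply(function(rg, site)
      truth[[match(rg, regions)]][[site]], rod$region, rod$site)
    rod$treatment <- an$treatment
    rod
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Volumetry study: Cavalieri estimates per IHC animal
#'
#' @inheritParams dcx_ihc_study
#' @param last_section_rule passed to [cavalieri_volumes()].
#' @return list: \code{volumes} (per animal/region/subfield with truth and
#'   treatment), \code{outlines} (the generated outline table).
#' @export
volume_study <- function(cohort, config,
                         last_section_rule = c("paper", "interval")) {
  last_section_rule <- match.arg(last_section_rule)
  ihc <- cohort[cohort$arm == "IHC", ]
  outl <- list(); truth <- list()
  for (i in seq_len(nrow(ihc))) {
    o <- generate_outlines(ihc[i, ], config)
    truth[[i]] <- attr(o, "truth")
    outl[[i]] <- o
  }
  outlines <- do.call(rbind, outl)
  vols <- cavalieri_volumes(outlines, last_section_rule)
  vols <- merge(vols, do.call(rbind, truth),
                by = c("animal_id", "region", "subfield"))
  vols$treatment <- ihc$treatment[match(vols$animal_id, ihc$animal_id)]
  list(volumes = vols, outlines = outlines)
}

#' Activity and molecular study: distances and normalized expression
#'
#' Generates activity logs plus molecular readouts, estimates per-mouse
#' running distances via spin allocation, quantifies Cq tables against the
#' fitted standard curves, and normalizes everything to Prox1.
#'
#' @inheritParams dcx_ihc_study
#' @return list: \code{distances} (estimated, with truth), \code{mrna} and
#'   \code{protein} normalized tables (with treatment and distance merged
#'   in), \code{raw} (the generated tables).
#' @export
activity_expression_study <- function(cohort, config) {
  gen <- generate_activity_and_expression(cohort, config)
  dist <- total_distance(gen$activity, config$wheel_circumference_m)
  dist <- merge(dist, gen$truth$distance, by = "animal_id", all.x = TRUE)
  mrna_q <- quantify_expression(gen$expression, gen$standards)
  mrna <- normalize_expression(mrna_q, "mRNA")
  prot <- normalize_expression(gen$protein, "protein")
  add_meta <- function(x) {
    x$treatment <- cohort$treatment[match(x$animal_id, cohort$animal_id)]
    x$cage_id <- cohort$cage_id[match(x$animal_id, cohort$animal_id)]
    x$distance_km <- dist$distance_km[match(x$animal_id, dist$animal_id)]
    x
  }
  list(distances = dist, mrna = add_meta(mrna), protein = add_meta(prot),
       raw = gen)
}

#' Enriched/control fold-change recovery table
#'
#' Cohort means per treatment and their E/C ratio for dorsal and ventral
#' regions, next to the configured generating effect.
#'
#' @param data data.frame with \code{region}, \code{treatment} and the value
#'   column.
#' @param value_col name of the value column.
#' @param configured named list/vector of generating folds per region.
#' @return data.frame: region, mean_E, mean_C, fold_EC, configured.
#' @export
fold_recovery <- function(data, value_col, configured) {
  out <- lapply(c("dorsal", "ventral"), function(rg) {
    sub <- data[data$region == rg, ]
    m_e <- mean(sub[[value_col]][sub$treatment == "E"])
    m_c <- mean(sub[[value_col]][sub$treatment == "C"])
    data.frame(region = rg, mean_E = m_e, mean_C = m_c,
               fold_EC = m_e / m_c, configured = configured[[rg]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

analysis_block <- function(name, data, formula, cluster = "animal_id",
                           value_col = "value", recovery = NULL,
                           posthoc_factors = c("treatment", "region")) {
  scr <- screen_outliers(data, value_col = value_col,
                         by = intersect(c("treatment", "region"), names(data)))
  kept <- scr[!scr$outlier, , drop = FALSE]
  fit <- dg_gee(formula, kept, id = cluster)
  ph <- tryCatch(lsd_posthoc(fit, posthoc_factors), error = function(e) NULL)
  list(name = name, n_outliers = sum(scr$outlier), fit = fit,
       wald_table = fit$wald_table, posthoc = ph, recovery = recovery,
       data = kept)
}

#' Run the full synthetic study end to end
#'
#' Generates a complete cohort under the configuration, runs every
#' quantification stage (DCX image analysis, BDNF densitometry, Cavalieri
#' volumetry, distance allocation, molecular normalization), screens
#' outliers per treatment-by-region cell, and fits the six headline
#' repeated-measures analyses (DCX IHC / mRNA / protein, BDNF IHC / mRNA,
#' volumes), each reported as a Wald test table, LSD post-hoc comparisons
#' and a recovery-vs-truth table. When \code{out_dir} is given, all tables
#' are written as CSV and hashed into the manifest.
#'
#' @param config a [generator_config()].
#' @param out_dir optional directory for CSV outputs.
#' @return list with \code{manifest} (seed, config, timings, hashes) and
#'   \code{analyses} (named list of six analysis blocks).
#' @export
run_full_study <- function(config, out_dir = NULL) {
  validate_generator_config(config)
  t0 <- Sys.time()
  cohort <- generate_cohort(config)
  dcx <- dcx_ihc_study(cohort, config)
  rod <- bdnf_rod_study(cohort, config)
  vol <- volume_study(cohort, config)
  mol <- activity_expression_study(cohort, config)

  analyses <- list(
    dcx_ihc = analysis_block(
      "DCX immunoreactivity (normalized area fraction)", dcx,
      normalized ~ treatment * region, value_col = "normalized",
      recovery = fold_recovery(dcx, "normalized", config$dcx_fold_enriched)),
    dcx_mrna = analysis_block(
      "Dcx mRNA / Prox1", mol$mrna,
      normalized_dcx ~ treatment * region, value_col = "normalized_dcx",
      recovery = fold_recovery(mol$mrna, "normalized_dcx",
                               config$dcx_fold_enriched)),
    dcx_protein = analysis_block(
      "DCX protein / PROX1", mol$protein,
      normalized_dcx ~ treatment * region, value_col = "normalized_dcx",
      recovery = fold_recovery(mol$protein, "normalized_dcx",
                               config$protein_fold)),
    bdnf_ihc = analysis_block(
      "BDNF ROD (background corrected)", rod,
      rod_corrected ~ treatment * region + site, value_col = "rod_corrected",
      recovery = fold_recovery(rod, "rod_corrected",
                               list(dorsal = NA_real_, ventral = NA_real_))),
    bdnf_mrna = analysis_block(
      "Bdnf mRNA / Prox1", mol$mrna,
      normalized_bdnf ~ treatment * region, value_col = "normalized_bdnf",
      recovery = fold_recovery(mol$mrna, "normalized_bdnf",
                               list(dorsal = 1, ventral = 1))),
    volumes = analysis_block(
      "Hippocampal volumes (Cavalieri)", vol$volumes,
      volume_mm3 ~ treatment * region * subfield + staining_method,
      value_col = "volume_mm3",
      recovery = {
        dv <- stats::aggregate(list(volume = vol$volumes$volume_mm3),
                               by = vol$volumes[c("animal_id", "region",
                                                  "treatment")], FUN = sum)
        fold_recovery(dv, "volume",
                      as.list(1 + config$volume_effect))
      }))

  # distance covariate analysis on the enriched PCR arm
  e_mrna <- mol$mrna[mol$mrna$treatment == "E" &
                       !is.na(mol$mrna$distance_km), ]
  r2 <- covariate_r2(e_mrna, "normalized_bdnf", "distance_km")
  dist_fit <- tryCatch(
    dg_gee(normalized_bdnf ~ region * distance_km, e_mrna, id = "animal_id"),
    error = function(e) NULL)
  analyses$bdnf_distance <- list(
    name = "Bdnf/Prox1 vs running distance (enriched)",
    r2 = r2, fit = dist_fit,
    wald_table = if (!is.null(dist_fit)) dist_fit$wald_table)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  tables <- list(cohort = cohort, dcx = dcx, rod = rod,
                 volumes = vol$volumes, outlines = vol$outlines,
                 distances = mol$distances, mrna = mol$mrna,
                 protein = mol$protein, activity = mol$raw$activity,
                 standards = mol$raw$standards)
  hashes <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(names(tables), function(nm) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], p, row.names = FALSE)
      p
    }, "")
    tools::md5sum(paths)
  } else {
    # structural digest: dimensions and value sums, stable under a fixed seed
    vapply(tables, function(t) {
      nums <- unlist(Filter(is.numeric, t))
      sprintf("%dx%d:%.10g", nrow(t), ncol(t),
              if (length(nums)) sum(nums) else 0)
    }, "")
  }
  manifest <- list(seed = config$seed, config = config,
                   timing_s = elapsed, hashes = hashes,
                   n_animals = nrow(cohort))
  list(manifest = manifest, analyses = analyses, tables = tables)
}

#' Validate pipeline input tables and frames
#'
#' Schema validation for the CSV tables and geometry validation for section
#' frames, with per-problem messages. Inputs may be data.frames or CSV file
#' paths; NULL inputs are skipped.
#'
#' @param animals,outlines,activity,expression,standards,protein tables or
#'   CSV paths.
#' @param frames optional list of \code{section_image} objects.
#' @return a data.frame (\code{input}, \code{message}) of problems; zero
#'   rows when everything validates.
#' @export
validate_inputs <- function(animals = NULL, outlines = NULL, activity = NULL,
                            expression = NULL, standards = NULL,
                            protein = NULL, frames = NULL) {
  required <- list(
    animals = c("animal_id", "batch", "cage_id", "treatment", "arm"),
    outlines = c("animal_id", "region", "subfield", "section_position_um",
                 "area_um2", "spacing_to_next_um"),
    activity = c("cage_id", "day", "window", "animal_id", "run_seconds",
                 "total_spins"),
    expression = c("animal_id", "region", "gene", "cq"),
    standards = c("gene", "quantity", "cq"),
    protein = c("animal_id", "region", "protein", "pg"))
  inputs <- list(animals = animals, outlines = outlines, activity = activity,
                 expression = expression, standards = standards,
                 protein = protein)
  problems <- list()
  note <- function(input, msg)
    problems[[length(problems) + 1L]] <<- data.frame(
      input = input, message = msg, stringsAsFactors = FALSE)
  for (nm in names(inputs)) {
    x <- inputs[[nm]]
    if (is.null(x)) next
    if (is.character(x)) {
      if (!file.exists(x)) { note(nm, sprintf("file not found: %s", x)); next }
      x <- utils::read.csv(x, stringsAsFactors = FALSE)
    }
    missing_cols <- setdiff(required[[nm]], names(x))
    if (length(missing_cols))
      note(nm, sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")))
    if (!nrow(x)) note(nm, "table has no rows")
  }
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "section_image")) {
      note("frames", sprintf("frame %d is not a section_image", i)); next
    }
    if (!identical(dim(f$pixels), dim(f$masks)))
      note("frames", sprintf("frame %d: mask shape mismatch", i))
    if (any(f$pixels < 0 | f$pixels > 255))
      note("frames", sprintf("frame %d: gray values outside [0, 255]", i))
  }
  if (!length(problems))
    return(data.frame(input = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}
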