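## Orchestration: seeded end-to-end runs (simulate -> label -> capture ->
## optional proximity ligation -> qPCR -> quantify) driven by a YAML/JSON
## scenario, with artifact writing and a fixture validation report. One
## master seed is expanded deterministically into per-stage seeds
## (spawnSeeds) so any stage can be rerun in isolation.

#' @noRd
.cfgGet <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

#' Tiny deterministic content hash (djb2) for provenance stamps.
#' @noRd
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Read an assay scenario configuration
#'
#' Scenario files are YAML (or JSON) with optional blocks `population`,
#' `labeling`, `capture`, `pla`, `qpcr`, `quantify`, and optionally
#' `measured` (a pre-measured DNA concentration that bypasses simulation).
#'
#' @param path YAML or JSON file.
#' @return the configuration as a named list.
#' @export
readScenario <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run the full assay pipeline on a scenario
#'
#' Executes population simulation, conjugate labeling, bead
#' capture/wash/elution, optional proximity ligation (`mode = "pla"`), Ct
#' simulation of a standard series plus target replicates, standard-curve
#' fitting, and quantification. When the scenario carries a `measured` block
#' (a reported DNA concentration and SD), the simulation stages are skipped
#' and only the conversion chain runs.
#'
#' @param config scenario list (see [readScenario()]) or a path to one.
#' @param seed master integer seed; expanded per stage via [spawnSeeds()].
#' @param mode `"direct"` (single conjugate, all reporter strands read out)
#'   or `"pla"` (dual conjugates; only ligated templates read out).
#' @param replicates qPCR replicates for the target wells.
#' @param output_dir optional directory; when given, writes `plate.csv`,
#'   `curve.json`, `result.json` and `report.md` there.
#' @return a list with elements `result` ([QuantResult]), `curve`
#'   ([StandardCurve]), `plate` (data.frame or NULL), `truth` (ground-truth
#'   list or NULL), `provenance` (seed, config hash, package version), and
#'   `paths` (written files, if any).
#' @examples
#' cfg <- readScenario(system.file("extdata", "worked_example.yaml",
#'                                 package = "evImmunoPCR"))
#' runPipeline(cfg, seed = 1)$result
#' @export
runPipeline <- function(config, seed = 1, mode = c("direct", "pla"),
                        replicates = 3, output_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- readScenario(config)
  stopifnot(replicates >= 1)
  seeds <- spawnSeeds(seed, 5L)
  prov <- list(seed = seed, config_hash = .configHash(config),
               package_version = as.character(packageVersion("evImmunoPCR")),
               mode = mode)

  qp <- config$qpcr
  curve_true <- standardCurve(
    slope = .cfgGet(config, "qpcr", "slope", 4.059),
    intercept = .cfgGet(config, "qpcr", "intercept", 8.144),
    x_range = range(.cfgGet(config, "qpcr", "standards_x", 0:4)))
  conc_at_x0 <- .cfgGet(config, "qpcr", "conc_at_x0", 10)
  noise_sd <- .cfgGet(config, "qpcr", "noise_sd", 0.2)
  max_cycles <- .cfgGet(config, "qpcr", "max_cycles", 40)
  dna_per_ab <- .cfgGet(config, "quantify", "dna_per_ab", 3)
  mw <- .cfgGet(config, "quantify", "mw", 29.1)

  if (!is.null(config$measured)) {
    result <- quantifyConcentration(config$measured$dna_conc,
                                    .cfgGet(config, "measured", "dna_sd", 0),
                                    dna_per_ab = dna_per_ab, mw = mw)
    out <- list(result = result, curve = curve_true, plate = NULL,
                truth = NULL, provenance = prov, paths = NULL)
    if (!is.null(output_dir)) out$paths <- .writeRunArtifacts(out, output_dir)
    return(out)
  }

  pop_params <- evPopulationParams(
    n_ev = .cfgGet(config, "population", "n_ev", 10000),
    tumor_fraction = .cfgGet(config, "population", "tumor_fraction", 0.8),
    antigen_mean = .cfgGet(config, "population", "antigen_mean", 50),
    antigen_dispersion = .cfgGet(config, "population", "antigen_dispersion", 5),
    nonspecific_rate = .cfgGet(config, "population", "nonspecific_rate", 0))
  pop <- simulatePopulation(pop_params, seed = seeds[1L])
  lab <- labelPopulation(
    pop, p_bind = .cfgGet(config, "labeling", "p_bind", 0.3),
    dual_label = (mode == "pla"),
    nonspecific_rate = pop_params@nonspecific_rate,
    dna_per_conjugate = .cfgGet(config, "labeling", "dna_per_conjugate", 3),
    seed = seeds[2L])
  sample <- captureWashElute(
    lab,
    capture_eff = .cfgGet(config, "capture", "capture_eff", 1),
    wash_retention = .cfgGet(config, "capture", "wash_retention", 1),
    eluate_volume_ul = .cfgGet(config, "capture", "eluate_volume_ul", 50),
    seed = seeds[3L])

  if (mode == "pla") {
    pla_cfg <- plaConfig(
      p_ligate = .cfgGet(config, "pla", "p_ligate", 0.9),
      background_rate = .cfgGet(config, "pla", "background_rate", 0))
    pla_out <- simulatePLA(sample, pla_cfg, seed = seeds[4L])
    readout_conc <- .strandsToNanomolar(templateCount(pla_out),
                                        sample@eluate_volume_ul)
  } else {
    pla_out <- NULL
    readout_conc <- trueDnaConc(sample)
  }

  std_x <- .cfgGet(config, "qpcr", "standards_x", 0:4)
  std_ct <- simulateCt(rep(std_x, each = replicates), curve_true,
                       noise_sd = noise_sd, max_cycles = max_cycles,
                       seed = seeds[5L])
  tgt_ct <- simulateCt(rep(concToX(readout_conc, conc_at_x0), replicates),
                       curve_true, noise_sd = noise_sd,
                       max_cycles = max_cycles,
                       seed = seeds[5L] %% .Machine$integer.max + 1L)
  plate <- rbind(
    qpcrPlate("standard", std_ct, dilution_x = rep(std_x, each = replicates)),
    qpcrPlate("target", tgt_ct))
  plate$well <- paste0("W", seq_len(nrow(plate)))
  curve_fit <- fitStandardCurve(plate$dilution_x[plate$target == "standard"],
                                plate$ct[plate$target == "standard"])
  result <- quantifyRun(plate, curve_fit, conc_at_x0 = conc_at_x0,
                        dna_per_ab = dna_per_ab, mw = mw)

  truth <- list(dna_conc_true = trueDnaConc(sample),
                readout_conc_true = readout_conc,
                antigen_mass_true = antibodyToMass(
                  dnaToAntibody(trueDnaConc(sample), dna_per_ab), mw),
                n_ev_surviving = nrow(sampleEVs(sample)),
                pla = if (!is.null(pla_out))
                  list(templates = pla_out@templates,
                       from_ev = pla_out@from_ev,
                       from_background = pla_out@from_background))
  out <- list(result = result, curve = curve_fit, plate = plate,
              truth = truth, provenance = prov, paths = NULL)
  if (!is.null(output_dir)) out$paths <- .writeRunArtifacts(out, output_dir)
  out
}

#' @noRd
.writeRunArtifacts <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(run$plate)) {
    paths$plate <- file.path(output_dir, "plate.csv")
    writePlate(run$plate, paths$plate)
  }
  paths$curve <- file.path(output_dir, "curve.json")
  writeCurve(run$curve, paths$curve)
  r <- run$result
  paths$result <- file.path(output_dir, "result.json")
  jsonlite::write_json(
    list(dna_conc_nM = r@dna_conc, dna_sd_nM = r@dna_sd,
         ab_conc_nM = r@ab_conc, ab_sd_nM = r@ab_sd,
         antigen_mass_ng_per_ml = r@antigen_mass,
         antigen_mass_sd_ng_per_ml = r@antigen_mass_sd,
         mw_kDa = r@mw, dna_per_ab = r@dna_per_ab,
         truth = run$truth, provenance = run$provenance),
    paths$result, auto_unbox = TRUE, digits = NA, null = "null")
  paths$report <- file.path(output_dir, "report.md")
  lines <- c(
    "# Assay run report", "",
    sprintf("- seed: %s; config hash: %s; package: evImmunoPCR %s; mode: %s",
            run$provenance$seed, run$provenance$config_hash,
            run$provenance$package_version, run$provenance$mode),
    sprintf("- reporter DNA: %.2f +/- %.2f nM", r@dna_conc, r@dna_sd),
    sprintf("- antibody/antigen: %.2f +/- %.2f nM", r@ab_conc, r@ab_sd),
    sprintf("- antigen mass: %s +/- %s ng/mL (MW %.4g kDa)",
            signif(r@antigen_mass, 3), signif(r@antigen_mass_sd, 3), r@mw))
  if (!is.null(run$truth))
    lines <- c(lines,
      sprintf("- ground truth: DNA %.4g nM; antigen mass %.4g ng/mL",
              run$truth$dna_conc_true, run$truth$antigen_mass_true),
      sprintf("- relative error on antigen mass: %.2f%%",
              100 * abs(r@antigen_mass - run$truth$antigen_mass_true) /
                run$truth$antigen_mass_true))
  writeLines(lines, paths$report)
  paths
}

#' Validate the packaged oligo fixture and the conjugate model constants
#'
#' Re-runs every sequence-level check the assay design implies on the
#' packaged oligo table — the C1+C2 ligation product matches the full-length
#' template, primer and probe sitings, the 69-mer length — plus the
#' analytic multivalency check on the conjugation statistics. Documented
#' known discrepancies (the EXO reverse primer's mismatch against the
#' 69-mer 3' end; the mix-arithmetic antibody:streptavidin ratio of 1:8
#' versus the quoted 1:80) are reported as warnings, not failures.
#'
#' @param oligos the oligo collection to validate; defaults to the packaged
#'   table ([assayOligos()]). Supplying a modified collection lets a check
#'   failure be exercised deliberately.
#' @return a `data.frame` with columns `check`, `status`
#'   (`pass`/`fail`/`warn`) and `detail`, with attribute `"ok"` set to
#'   `TRUE` when no check failed.
#' @examples
#' validateFixtures()
#' @export
validateFixtures <- function(oligos = assayOligos()) {
  res <- list()
  add <- function(check, ok, detail = "", warn = FALSE) {
    res[[length(res) + 1L]] <<- data.frame(
      check = check,
      status = if (warn) "warn" else if (ok) "pass" else "fail",
      detail = detail, stringsAsFactors = FALSE)
  }
  seqs <- setNames(as.character(oligos), names(oligos))

  add("fixture_record_count", length(oligos) == 13L,
      sprintf("%d records (expected 13)", length(oligos)))
  add("sixtyninemer_length", nchar(seqs[["EXOpcr-69-bio"]]) == 69L,
      sprintf("%d nt", nchar(seqs[["EXOpcr-69-bio"]])))
  lig <- try(ligateOligos(oligos, "Proximity_C1", "Proximity_C2",
                          "Proximity_cnct"), silent = TRUE)
  lig_ok <- !inherits(lig, "try-error") &&
    identical(as.character(lig[[1]]), seqs[["C1C2"]])
  add("c1c2_ligation", lig_ok, "C1+C2 concatenation equals the C1C2 record")
  add("proximity_f_in_c1",
      grepl(seqs[["Proximity_F"]], seqs[["Proximity_C1"]], fixed = TRUE),
      "forward primer sits in C1")
  add("proximity_r_in_c2",
      grepl(revComp(seqs[["Proximity_R"]]), seqs[["Proximity_C2"]],
            fixed = TRUE),
      "reverse-complemented reverse primer sits in C2")
  add("probe_in_sixtyninemer",
      grepl(revComp(seqs[["Probe-Rox"]]), seqs[["EXOpcr-69-bio"]],
            fixed = TRUE),
      "reverse-complemented ROX probe sits in the 69-mer")
  add("exof_prefix", startsWith(seqs[["EXOpcr-69-bio"]], seqs[["EXO-F"]]),
      "EXO forward primer is a prefix of the 69-mer")
  amp <- try(findAmplicon(oligos, "C1C2", "Proximity_F", "Proximity_R"),
             silent = TRUE)
  add("c1c2_amplicon_87",
      !inherits(amp, "try-error") && ampliconLength(amp) == 87L,
      "proximity primer pair spans 87 nt on C1C2")
  add("bio_c1_in_c1",
      grepl(seqs[["Bio-proximity_C1"]], seqs[["Proximity_C1"]], fixed = TRUE),
      "biotinylated C1 is a 3' fragment of C1")
  add("multivalency_formula",
      isTRUE(all.equal(signif(probMultivalentAntibody(1 / 80), 2), 7.7e-5)),
      "P(>1 antibody per streptavidin) at lambda = 1/80 rounds to 7.7e-5")

  exo_amp <- try(findAmplicon(oligos, "EXOpcr-69-bio", "EXO-F", "EXO-R"),
                 silent = TRUE)
  add("exo_r_known_mismatch", TRUE, warn = inherits(exo_amp, "try-error"),
      detail = paste("reverse-complemented EXO-R does not exactly match the",
                     "69-mer 3' end (documented design-table discrepancy)"))
  lam_mix <- lambdaFromMix(conjugationMix())
  add("mix_ratio_known_discrepancy", TRUE, warn = abs(lam_mix - 1/80) > 1e-6,
      detail = sprintf(paste("mix arithmetic gives lambda = %.4g (1:%g);",
                             "the quoted ratio is 1:80"),
                       lam_mix, round(1 / lam_mix)))

  out <- do.call(rbind, res)
  attr(out, "ok") <- !any(out$status == "fail")
  out
}
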