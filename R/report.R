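#' Read a run configuration from a key-value text file
#'
#' Lines of the form `key = value`; `#` comments and blank lines are
#' ignored.  Comma-separated values become vectors; numerics are
#' converted.  Referenced files are checked at read time.
#'
#' @param path Config file path, or `NULL` for the documented defaults.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(pocket_cutoff = 5, clash_tolerance = 0.4, scan_step = 1,
              gate_threshold = 1.4, seed = 1, n_constructs = 10,
              structures = character())
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) abort(paste0("malformed config line: ", ln))
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      vals <- trimws(strsplit(val, ",")[[1]])
      num <- suppressWarnings(as.numeric(vals))
      cfg[[key]] <- if (!anyNA(num)) num else vals
    }
  }
  if (length(cfg$structures) > 0) {
    missing <- cfg$structures[!file.exists(cfg$structures)]
    if (length(missing) > 0)
      abort(paste0("config references missing file(s): ",
                   paste(missing, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

config_provenance <- function(config) {
  list(tool = "chanalyze", version = as.character(packageVersion("chanalyze")),
       config = unclass(config), config_hash = rlang::hash(unclass(config)),
       input_checksums = if (length(config$structures) > 0)
         as.list(tools::md5sum(config$structures)) else list())
}

#' Built-in demonstration structure pair
#'
#' Two synthetic C4 helix bundles standing in for an apo and a
#' ligand-bound channel: the bound form carries a pseudo-atom ligand
#' wedged between two chains, one pocket leucine rotated to chi1 = 173
#' degrees (vs -72 in the apo form), and a progressive twist of the last
#' helical turns emulating a C-terminal displacement.
#'
#' @return List with `apo` and `bound` `chan_structure`s and the pocket
#'   residue id (`chain`, `resi`).
#' @export
demo_structures <- function() {
  seqs <- rep(c("LEU", "PHE", "SER", "VAL", "LEU", "GLY"), length.out = 24)
  seqs[12] <- "LEU"   # the pocket residue must have a chi1
  mk <- function(chi_pocket, id) {
    chi <- rep(-60, 24)
    chi[12] <- chi_pocket
    build_helix_bundle(4, radius = 10, residues_per_helix = 24,
                       sequence = seqs, chi1 = chi, id = id)
  }
  apo <- mk(-72, "demo_apo")
  bound <- mk(173, "demo_bound")
  # ligand midway between chains A and B near residue 12's level
  ca <- select_atoms(bound, "chain A and resi 12 and name CA")
  cb <- select_atoms(bound, "chain B and resi 12 and name CA")
  mid <- (coords(ca) + coords(cb)) / 2
  lig <- tibble(atom = paste0("C", 1:4), element = "C",
                x = mid[1] + c(-1.5, 0, 1.5, 3.0), y = mid[2],
                z = mid[3] + c(0, 1, 0, 1))
  bound <- build_helix_bundle(4, radius = 10, residues_per_helix = 24,
                              sequence = seqs,
                              chi1 = {ch <- rep(-60, 24); ch[12] <- 173; ch},
                              ligand = lig, id = "demo_bound")
  # twist the top of the bundle (residues 21-24) progressively in the apo
  a <- as_tibble(apo)
  for (r in 21:24) {
    idx <- a$resi == r
    Rz <- rotation_about(c(0, 0, 1), (r - 20) * 1.6)
    a[idx, c("x", "y", "z")] <- as.data.frame(transform_xyz(coords(a[idx, ]), Rz))
  }
  apo <- new_structure(a, id = "demo_apo", source_format = "synthetic")
  list(apo = apo, bound = bound, pocket_chain = "A", pocket_resi = 12L)
}

#' Run the structural analysis report
#'
#' Composes the structural stages on the configured structures (or the
#' built-in demonstration fixtures): ligand pocket table, chi1 table over
#' all protomers with a spread flag, a chi1 clash scan of the pocket
#' residue, the apo-vs-bound displacement map, and pore profiles with gate
#' calls.  Deterministic for a given config.
#'
#' @param config A [read_run_config()] result (or `NULL` for defaults).
#' @param out_dir Optional directory for JSON/TSV output.
#' @return A `structural_report` list with all sections and provenance.
#' @export
run_structural_report <- function(config = read_run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  crit <- clash_criterion(tolerance = config$clash_tolerance)
  if (length(config$structures) >= 2) {
    bound <- read_structure(config$structures[1])
    apo <- read_structure(config$structures[2])
    lig <- ligand_instances(bound)[1, ]
    pocket <- lining_residues(bound, lig, cutoff = config$pocket_cutoff)
    scan_res <- pocket |> filter(.data$resn %in% names(.gamma_atom) |
                                   .data$resn == "LEU") |> head(1)
    scan_chain <- scan_res$chain; scan_resi <- scan_res$resi
  } else {
    demo <- demo_structures()
    bound <- demo$bound; apo <- demo$apo
    lig <- ligand_instances(bound)[1, ]
    pocket <- lining_residues(bound, lig, cutoff = config$pocket_cutoff)
    scan_chain <- demo$pocket_chain; scan_resi <- demo$pocket_resi
  }
  chi <- chi1_table(bound)
  spread <- chi |>
    filter(!is.na(.data$chi1)) |>
    group_by(.data$resi, .data$resn) |>
    summarise(n_protomers = dplyr::n(),
              spread_deg = max(.data$chi1) - min(.data$chi1),
              .groups = "drop") |>
    mutate(flagged = .data$spread_deg > 2)
  scan <- chi1_clash_scan(bound, scan_chain, scan_resi,
                          environment = sprintf("protein and heavy"),
                          criterion = crit, step = config$scan_step)
  disp <- displacement_map(bound, apo, anchor = "resi 1-16",
                           atom_rule = c("CA", "sidechain_centroid"))
  prof_bound <- pore_profile(bound)
  prof_apo <- pore_profile(apo)
  report <- list(
    provenance = config_provenance(config),
    pocket = as_tibble(pocket),
    chi1 = chi, chi1_spread = spread,
    scan = list(residue = sprintf("%s/%d", scan_chain, scan_resi),
                allowed_intervals = scan$allowed_intervals,
                onsets = scan$onsets, tolerance = crit$tolerance),
    displacement = disp,
    pore = list(bound = list(min = min_pore_radius(prof_bound),
                             gate = gate_state(prof_bound)),
                apo = list(min = min_pore_radius(prof_apo),
                           gate = gate_state(prof_apo))))
  class(report) <- "structural_report"
  if (!is.null(out_dir)) write_report(report, out_dir, "structural")
  report
}

#' Run the electrophysiology analysis report
#'
#' Simulates (or loads) the construct cohort, analyzes tails and fold
#' changes, fits control/activator conductance-voltage Boltzmanns for the
#' base model, computes the cohort rank correlation, and fits the
#' single-channel amplitude histogram.  Stochastic stages are seeded from
#' the config; analytic stages are seed-independent.
#'
#' @param config A [read_run_config()] result (or `NULL` for defaults).
#' @param out_dir Optional directory for JSON/TSV output.
#' @return An `ephys_report` list.
#' @export
run_ephys_report <- function(config = read_run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  seed <- as.integer(config$seed)
  cohort <- simulate_cohort(n_constructs = config$n_constructs, seed = seed)
  resp <- drug_response_table(cohort)
  wt <- builtin_model("wt")
  gv_ctrl <- simulate_gv(wt)
  gv_drug <- simulate_gv(apply_modifier(wt, activator_modifier()))
  fit_ctrl <- fit_boltzmann(gv_ctrl)
  fit_drug <- fit_boltzmann(gv_drug)
  sc_model <- builtin_model("stable_open", n_channels = 1)
  sc <- simulate_single_channel(
    sc_model, voltage_protocol(tibble(duration = 5, voltage = 60),
                               rate = 5000),
    noise_sd = 0.05, filter_cutoff = 200, seed = seed)
  hist <- amplitude_histogram(sc)
  report <- list(
    provenance = config_provenance(config),
    cohort = cohort,
    correlation = resp$correlation,
    boltzmann = list(control = tidy.boltzmann_fit(fit_ctrl),
                     drug = tidy.boltzmann_fit(fit_drug),
                     shift_mV = fit_drug$v_half - fit_ctrl$v_half),
    single_channel = list(open_peak_pA = hist$open_peak,
                          components = hist$components, flag = hist$flag))
  class(report) <- "ephys_report"
  if (!is.null(out_dir)) write_report(report, out_dir, "ephys")
  report
}

write_report <- function(report, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, paste0(stem, "_report.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x))
      utils::write.table(x, file.path(out_dir, paste0(stem, "_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

report_to_json <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, report_to_json))
  x
}
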