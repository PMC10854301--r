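#' Read a run configuration
#'
#' Run configurations are plain YAML.  Minimal example:
#'
#' ```yaml
#' structures:
#'   a: open.pdb          # numerator structure
#'   b: closed.pdb        # denominator structure
#' chain_pairs:           # chain in a -> chain in b
#'   A: A
#'   B: B
#' output_dir: out
#' ```
#'
#' Optional blocks `sasa`, `diff`, `cavity`, `contacts` override the
#' corresponding parameter defaults; `selections` names reusable
#' selection expressions; `interface` restricts the differential table
#' to residues in contact across two selections; `measurements` lists
#' distances, hydrogen-bond and proline-pucker calls.  Every defaulted
#' value is written back into the run manifest.
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

validate_config <- function(config) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (is.null(config$structures) || is.null(config$structures$a) ||
      is.null(config$structures$b))
    fail("structures$a and structures$b are required")
  if (is.null(config$chain_pairs) || length(config$chain_pairs) == 0)
    fail("chain_pairs is required (map of chain in a -> chain in b)")
  invisible(config)
}

config_structure <- function(x, label) {
  if (inherits(x, "structure3d")) return(x)
  if (is.character(x)) return(read_structure(x, id = label))
  stop("config error: structures$", label,
       " must be a file path or structure3d", call. = FALSE)
}

build_params <- function(config) {
  s <- config$sasa %||% list()
  d <- config$diff %||% list()
  cv <- config$cavity %||% list()
  ct <- config$contacts %||% list()
  list(
    sasa = sasa_params(
      probe_radius = s$probe_radius %||% 1.4,
      n_points = s$n_points %||% 960,
      include_hetero = s$include_hetero %||% FALSE,
      include_hydrogens = s$include_hydrogens %||% FALSE),
    reference_table = s$reference_table %||% "tien2013",
    diff = diff_params(
      exclusion_delta = d$exclusion_delta %||% 2.5,
      ratio_mode = d$ratio_mode %||% "relative_percent",
      epsilon_area = d$epsilon_area %||% 0.1),
    scheme = classification_scheme(),
    cavity = cavity_params(
      grid_spacing = cv$grid_spacing %||% 0.5,
      probe_radius = cv$probe_radius %||% 1.4,
      detection_multiplier = cv$detection_multiplier %||% 3,
      cutoff_multiplier = cv$cutoff_multiplier %||% 4,
      min_volume = cv$min_volume %||% 5),
    contacts = contact_params(cutoff = ct$cutoff %||% 4.0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_selection <- function(expr, config) {
  if (!is.null(config$selections) && expr %in% names(config$selections))
    config$selections[[expr]] else expr
}

#' Run a two-structure comparison
#'
#' Executes the full comparison pipeline the package exists for:
#' per-residue SASA on both structures, residue correspondence, the
#' differential SASA ratio table with exclusions and fold bins,
#' optional restriction to interface (contact) residues, cavity
#' detection on both structures, and any configured point
#' measurements (CA distances, hydrogen bonds, proline pucker).
#' Writes TSV/JSON tables, a B-factor-encoded PDB of structure `a`
#' carrying the fold ratios, a colouring script, and a `manifest.json`
#' recording every parameter (including defaults) so the run can be
#' reproduced bit-identically.
#'
#' @param config configuration list (see [read_run_config()]) or path
#'   to a YAML file.
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, a list with the in-memory results (`sasa_a`,
#'   `sasa_b`, `correspondence`, `diff`, `interface`, `cavities_a`,
#'   `cavities_b`, `measurements`, `manifest`).
#' @export
run_comparison <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop(
    "config error: output_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- build_params(config)

  sa <- config_structure(config$structures$a, "a")
  sb <- config_structure(config$structures$b, "b")

  sasa_a <- calc_sasa(sa, p$sasa, p$reference_table)
  sasa_b <- calc_sasa(sb, p$sasa, p$reference_table)
  write_sasa_tsv(sasa_a, file.path(out_dir, "residue_sasa_a.tsv"))
  write_sasa_tsv(sasa_b, file.path(out_dir, "residue_sasa_b.tsv"))

  corr <- align_residues(sa, sb, config$chain_pairs)
  dt <- sasa_ratio_table(sasa_a, sasa_b, corr, p$diff, p$scheme)
  write_diff_tsv(dt, file.path(out_dir, "differential.tsv"))
  write_color_script(dt, file.path(out_dir, "coloring.pml"))

  ratios <- dt$rows$ratio
  ratios[dt$rows$excluded] <- NA
  vals <- ifelse(is.na(ratios), -1, pmin(ratios, 999))
  names(vals) <- dt$rows$key_a
  write_annotated(sa, stats::setNames(vals, dt$rows$key_a),
                  file.path(out_dir, "a_ratio_bfactor.pdb"), sentinel = -1)

  iface <- NULL
  if (!is.null(config$interface)) {
    ic <- config$interface
    on <- ic$structure %||% "b"
    struc <- if (on == "a") sa else sb
    cl <- contacts(struc,
                   resolve_selection(ic$sel_a, config),
                   resolve_selection(ic$sel_b, config), p$contacts)
    touched <- unique(rbind(
      stats::setNames(cl$residue_pairs[, c("chain_a", "resno_a", "resid_a")],
                      c("chain", "resno", "resid")),
      stats::setNames(cl$residue_pairs[, c("chain_b", "resno_b", "resid_b")],
                      c("chain", "resno", "resid"))))
    iface <- interface_diff(dt, touched, side = on)
    write_diff_tsv(iface, file.path(out_dir, "interface_differential.tsv"))
  }

  cav_a <- detect_cavities(sa, p$cavity)
  cav_b <- detect_cavities(sb, p$cavity)
  write_cavity_json(cav_a, file.path(out_dir, "cavities_a.json"))
  write_cavity_json(cav_b, file.path(out_dir, "cavities_b.json"))

  meas <- run_measurements(config, list(a = sa, b = sb), p)
  if (length(meas))
    jsonlite::write_json(meas, file.path(out_dir, "measurements.json"),
                         auto_unbox = TRUE, digits = NA)

  summary <- list(
    structure_a = sa$id, structure_b = sb$id,
    n_pairs = nrow(dt$rows), bin_counts = as.list(bin_counts(dt)),
    interface_bin_counts = if (!is.null(iface)) as.list(iface$summary),
    total_cavity_volume_a = cav_a$total_volume,
    total_cavity_volume_b = cav_b$total_volume)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    tool = "strucdiff",
    version = as.character(utils::packageVersion("strucdiff")),
    structures = list(
      a = if (is.character(config$structures$a)) config$structures$a else sa$id,
      b = if (is.character(config$structures$b)) config$structures$b else sb$id),
    chain_pairs = config$chain_pairs,
    sasa = list(probe_radius = p$sasa$probe_radius,
                n_points = p$sasa$n_points,
                radii_set = p$sasa$radii$name,
                include_hetero = p$sasa$include_hetero,
                include_hydrogens = p$sasa$include_hydrogens,
                reference_table = p$reference_table),
    diff = list(exclusion_delta = p$diff$exclusion_delta,
                ratio_mode = p$diff$ratio_mode,
                epsilon_area = p$diff$epsilon_area,
                bin_edges = p$scheme$edges),
    cavity = list(grid_spacing = p$cavity$grid_spacing,
                  probe_radius = p$cavity$probe_radius,
                  detection_multiplier = p$cavity$detection_multiplier,
                  cutoff_multiplier = p$cavity$cutoff_multiplier,
                  min_volume = p$cavity$min_volume,
                  radii_set = p$cavity$radii$name),
    contacts = list(cutoff = p$contacts$cutoff),
    interface = config$interface,
    selections = config$selections,
    measurements = config$measurements)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(sasa_a = sasa_a, sasa_b = sasa_b, correspondence = corr,
                 diff = dt, interface = iface, cavities_a = cav_a,
                 cavities_b = cav_b, measurements = meas,
                 manifest = manifest, output_dir = out_dir))
}

run_measurements <- function(config, strucs, p) {
  m <- config$measurements
  if (is.null(m)) return(list())
  out <- list()
  for (d in m$distances %||% list()) {
    struc <- strucs[[d$structure %||% "a"]]
    val <- ca_distance(struc,
                       residue_ref(d$from$chain, d$from$resno,
                                   d$from$insert %||% ""),
                       residue_ref(d$to$chain, d$to$resno,
                                   d$to$insert %||% ""))
    out$distances <- c(out$distances, list(list(
      structure = d$structure %||% "a", from = d$from, to = d$to,
      ca_distance = val)))
  }
  for (d in m$pucker %||% list()) {
    struc <- strucs[[d$structure %||% "a"]]
    pc <- proline_pucker(struc, residue_ref(d$chain, d$resno,
                                            d$insert %||% ""))
    out$pucker <- c(out$pucker, list(list(
      structure = d$structure %||% "a", chain = d$chain, resno = d$resno,
      state = pc$state, cgamma_displacement = pc$cgamma_displacement)))
  }
  for (d in m$hbonds %||% list()) {
    struc <- strucs[[d$structure %||% "a"]]
    hb <- hydrogen_bonds(struc,
                         resolve_selection(d$sel_a, config),
                         resolve_selection(d$sel_b, config))
    out$hbonds <- c(out$hbonds, list(list(
      structure = d$structure %||% "a", sel_a = d$sel_a, sel_b = d$sel_b,
      n_bonds = nrow(hb$atoms), bonds = hb$atoms)))
  }
  for (d in m$contacts %||% list()) {
    struc <- strucs[[d$structure %||% "a"]]
    cl <- contacts(struc,
                   resolve_selection(d$sel_a, config),
                   resolve_selection(d$sel_b, config), p$contacts)
    out$contacts <- c(out$contacts, list(list(
      structure = d$structure %||% "a", sel_a = d$sel_a, sel_b = d$sel_b,
      n_atom_contacts = nrow(cl$atoms),
      n_residue_pairs = nrow(cl$residue_pairs))))
  }
  out
}
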