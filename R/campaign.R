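# End-to-end screening campaign: prepare, grid, dock, rescore survivors,
# triage, report. Resumable via a per-compound manifest.

#' Run a virtual-screening campaign
#'
#' Builds the potential grids once, docks every library compound, rescoring
#' (local optimization + binding enthalpy) only the compounds that pass the
#' score cutoff (set `rescore_all = TRUE` to rescore everything), applies the
#' screening funnel, and writes a ranked CSV, a JSON audit trail, a JSON-lines
#' log and per-compound pose SDFs under `out_dir`. Per-compound failures are
#' recorded and the campaign continues. Completed compounds are skipped on
#' rerun (manifest resume), and outputs are reproducible for a fixed seed.
#'
#' @param receptor A `gridock_receptor` or a PDB path.
#' @param ligands A list of `gridock_ligand` objects or a ligand file path.
#' @param out_dir Output directory.
#' @param grid_cfg A [grid_config()]; defaults to a cube at the receptor's
#'   centre hint.
#' @param ga A [ga_config()]; its seed is overridden per compound from
#'   `seed`.
#' @param thresholds A [screening_thresholds()].
#' @param pockets Pocket list from [read_pockets()], or `NULL` to skip the
#'   pocket-occupancy stage.
#' @param backend Enthalpy backend; default [forcefield_backend()].
#' @param rescore_all Rescore every compound rather than only score-stage
#'   survivors.
#' @param seed Master campaign seed.
#' @param resume Skip compounds already present in the manifest.
#' @param native Native-ligand residue name passed to [read_receptor()] when
#'   `receptor` is a path.
#' @return A `gridock_campaign`: `results` tibble, `funnel`, and the output
#'   paths.
#' @export
screen_campaign <- function(receptor, ligands, out_dir,
                            grid_cfg = NULL, ga = ga_config(),
                            thresholds = screening_thresholds(),
                            pockets = NULL,
                            backend = forcefield_backend(),
                            rescore_all = FALSE, seed = 1, resume = TRUE,
                            native = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man_dir <- file.path(out_dir, "manifest")
  dir.create(man_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "campaign.log.jsonl")
  log_event <- function(...) {
    ev <- list(...)
    ev$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    cat(jsonlite::toJSON(ev, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE)
  }

  if (is.character(receptor)) receptor <- read_receptor(receptor, native = native)
  if (is.character(ligands)) ligands <- read_ligands(ligands)
  nm <- map(ligands, "name")
  if (anyDuplicated(unlist(nm))) {
    nm <- as.list(make.unique(unlist(nm)))
    for (k in seq_along(ligands)) ligands[[k]]$name <- nm[[k]]
  }

  if (length(ligands) == 0) {
    inform("Empty ligand library: writing an empty report.")
    empty <- funnel(tibble(compound = character(0), score = numeric(0)))
    utils::write.csv(tibble(), file.path(out_dir, "ranked.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(), file.path(out_dir, "audit.json"))
    return(structure(list(results = tibble(), funnel = empty,
                          out_dir = out_dir, n_compounds = 0L, seed = seed),
                     class = "gridock_campaign"))
  }

  if (is.null(grid_cfg)) grid_cfg <- grid_config(receptor$center_hint)
  log_event(event = "grid_build", seed = seed)
  grid <- build_grids(receptor, grid_cfg)

  lig_seeds <- .derive_seeds(seed, length(ligands))
  rows <- list()
  for (k in seq_along(ligands)) {
    lig <- ligands[[k]]
    man_file <- file.path(man_dir, paste0(lig$name, ".json"))
    if (resume && file.exists(man_file)) {
      row <- tryCatch({
        r <- jsonlite::read_json(man_file, simplifyVector = TRUE)
        stopifnot(is.data.frame(r), nrow(r) == 1)
        as_tibble(r)
      }, error = function(e) NULL)
      if (!is.null(row)) {
        rows[[k]] <- row
        log_event(event = "resume_skip", compound = lig$name)
        next
      }
    }
    row <- tryCatch({
      cfg <- ga
      cfg$seed <- lig_seeds[k]
      dres <- dock(grid, lig, cfg)
      pose_path <- file.path(out_dir, paste0(lig$name, "_pose.sdf"))
      write_ligands(lig, pose_path, coords = list(dres$best_coords))
      pocket_ok <- NA
      if (!is.null(pockets)) {
        occ <- pocket_occupancy(dres$best_coords, lig, pockets, receptor,
                                min_fraction = thresholds$pocket_min_fraction)
        pocket_ok <- all(occ$occupied[occ$pocket %in%
                                        thresholds$required_pockets])
      }
      dh <- NA_real_
      if (rescore_all || dres$score <= thresholds$score_cutoff) {
        opt <- local_optimize_ligand(backend, receptor, lig,
                                     start_coords = dres$best_coords)
        enth <- binding_enthalpy(backend, receptor, lig, opt$coords,
                                 unbound_conformers = list(lig$coords))
        dh <- enth$dH_bind
      }
      r <- tibble(compound = lig$name, score = dres$score,
                  objective = dres$objective,
                  strain = unname(dres$breakdown["strain"]),
                  first_cluster_population = dres$first_cluster_population,
                  n_clusters = length(dres$clusters),
                  success = dres$success,
                  pockets_occupied = pocket_ok,
                  dH_bind = dh, status = "ok")
      log_event(event = "compound_done", compound = lig$name,
                score = dres$score,
                first_cluster_population = dres$first_cluster_population,
                success = dres$success, dH_bind = dh)
      r
    }, error = function(e) {
      log_event(event = "compound_failed", compound = lig$name,
                message = conditionMessage(e))
      tibble(compound = lig$name, score = NA_real_, objective = NA_real_,
             strain = NA_real_, first_cluster_population = NA_integer_,
             n_clusters = NA_integer_, success = NA,
             pockets_occupied = NA, dH_bind = NA_real_, status = "error")
    })
    jsonlite::write_json(row, man_file, dataframe = "rows", na = "null",
                         digits = NA)
    rows[[k]] <- row
  }
  results <- bind_rows(rows)
  if (all(results$status == "error")) {
    abort("All compounds failed; see the campaign log.")
  }

  ok <- filter(results, .data$status == "ok")
  fin <- ok
  if (is.null(pockets)) fin$pockets_occupied <- NULL
  enth_tbl <- select(filter(fin, !is.na(.data$dH_bind)), "compound", "dH_bind")
  fn <- funnel(select(fin, -dplyr::any_of("dH_bind")), enth_tbl, thresholds)

  ranked <- left_join(fn$audit, select(results, "compound", "status"),
                      by = "compound")
  utils::write.csv(ranked, file.path(out_dir, "ranked.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = seed, thresholds = unclass(thresholds),
                            audit = fn$audit),
                       file.path(out_dir, "audit.json"), auto_unbox = TRUE,
                       digits = NA)
  log_event(event = "campaign_done", n = nrow(results),
            n_shortlist = nrow(fn$shortlist))
  structure(list(results = results, funnel = fn, out_dir = out_dir,
                 n_compounds = length(ligands), seed = seed),
            class = "gridock_campaign")
}

#' @export
print.gridock_campaign <- function(x, ...) {
  cat(sprintf("<gridock_campaign> %d compound(s), %d shortlisted -> %s\n",
              x$n_compounds, nrow(x$funnel$shortlist), x$out_dir))
  invisible(x)
}

#' @export
tidy.gridock_campaign <- function(x, ...) x$results

#' @export
glance.gridock_campaign <- function(x, ...) {
  tibble(n_compounds = x$n_compounds,
         n_ok = sum(x$results$status == "ok"),
         n_shortlist = nrow(x$funnel$shortlist), seed = x$seed)
}
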