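# Screening funnel (score / cluster / pocket / enthalpy ranking) and
# ADME & identity descriptors.

#' Screening thresholds
#'
#' @param score_cutoff Score cutoff (kcal/mol); compounds scoring worse
#'   (greater) than this are discarded at stage 1. Default -5.00.
#' @param min_first_cluster Minimum first-cluster population to survive
#'   stage 2. Default 13 (i.e. population strictly greater than 12).
#' @param required_pockets Character vector of pocket names that must all be
#'   occupied at stage 3.
#' @param pocket_min_fraction Minimum fraction of ligand heavy atoms in
#'   contact with a pocket for it to count as occupied. Default 0.05.
#' @param enthalpy_rank_keep Keep at most this many stage-4 survivors
#'   (Inf keeps all), ranked by binding enthalpy.
#' @return A `gridock_thresholds` list.
#' @export
screening_thresholds <- function(score_cutoff = -5.00, min_first_cluster = 13,
                                 required_pockets = c("S1", "S1p", "S3"),
                                 pocket_min_fraction = 0.05,
                                 enthalpy_rank_keep = Inf) {
  stopifnot(is.finite(score_cutoff), is.finite(min_first_cluster),
            is.finite(pocket_min_fraction))
  structure(as.list(environment()), class = "gridock_thresholds")
}

#' Pocket definitions
#'
#' Binding-site subsites defined by residue tags (`"ASP189"` style) and a
#' contact radius. A ready-made, editable definition of the factor XIIa
#' subsites (S1 specificity pocket around Asp-189, the catalytic-triad S1'
#' region, S2--S4) ships as a YAML file; see
#' `system.file("extdata", "pockets_fxiia.yaml", package = "gridock")`.
#'
#' @param path YAML file mapping pocket names to residue-tag lists; entries
#'   may include a `contact_radius` scalar (A), default 4.5.
#' @return A named list of `list(residues, contact_radius)`.
#' @export
read_pockets <- function(path = system.file("extdata", "pockets_fxiia.yaml",
                                            package = "gridock")) {
  raw <- yaml::read_yaml(path)
  radius <- raw$contact_radius %||% 4.5
  raw$contact_radius <- NULL
  out <- lapply(raw, function(v) {
    if (is.list(v)) {
      list(residues = unlist(v$residues), contact_radius = v$contact_radius %||% radius)
    } else list(residues = unlist(v), contact_radius = radius)
  })
  if (any(lengths(lapply(out, `[[`, "residues")) == 0)) {
    abort("Every pocket needs a nonempty residue list.")
  }
  out
}

#' Pocket occupancy of a ligand pose
#'
#' For each pocket, the fraction of ligand heavy atoms within the pocket's
#' contact radius of any atom of its residues.
#'
#' @param pose_coords Ligand coordinates (A).
#' @param topology The ligand `gridock_ligand` (identifies heavy atoms).
#' @param pockets Pocket list from [read_pockets()].
#' @param receptor The `gridock_receptor` the pockets refer to.
#' @return A tibble with `pocket`, `fraction`, `occupied` (fraction >=
#'   `min_fraction`).
#' @param min_fraction Occupancy threshold; default 0.05.
#' @export
pocket_occupancy <- function(pose_coords, topology, pockets, receptor,
                             min_fraction = 0.05) {
  L <- as.matrix(pose_coords)
  heavy <- topology$atoms$element != "H"
  Lh <- L[heavy, , drop = FALSE]
  ra <- receptor$atoms
  tags <- paste0(ra$residue, ra$resno)
  rows <- imap(pockets, function(p, nm) {
    unknown <- setdiff(p$residues, tags)
    if (length(unknown) > 0) {
      abort(sprintf("Pocket %s references unknown residue tag(s): %s", nm,
                    paste(unknown, collapse = ", ")))
    }
    sel <- tags %in% p$residues
    P <- receptor_coords(receptor)[sel, , drop = FALSE]
    frac <- if (nrow(Lh) == 0 || nrow(P) == 0) 0 else {
      mind <- apply(Lh, 1, function(x) min(colSums((t(P) - x)^2)))
      mean(mind <= p$contact_radius^2)
    }
    tibble(pocket = nm, fraction = frac, occupied = frac >= min_fraction)
  })
  bind_rows(rows)
}

#' Apply the screening funnel
#'
#' Stage 1 removes compounds scoring worse than the score cutoff; stage 2
#' removes compounds whose first docking cluster is under-populated; stage 3
#' removes compounds that fail required-pocket occupancy; stage 4 ranks the
#' survivors by binding enthalpy (ascending). An audit trail records the
#' stage at which every compound exited.
#'
#' @param docking_results Tibble with one row per compound: `compound`,
#'   `score`, `first_cluster_population`, and (when pocket filtering is
#'   requested) logical `pockets_occupied`.
#' @param enthalpy_reports Tibble with `compound` and `dH_bind`; required
#'   for every compound that survives stages 1--3.
#' @param thresholds A [screening_thresholds()] object.
#' @return A `gridock_funnel` with tibbles `shortlist` (ranked) and `audit`.
#' @export
funnel <- function(docking_results, enthalpy_reports = NULL,
                   thresholds = screening_thresholds()) {
  d <- as_tibble(docking_results)
  if (nrow(d) == 0) {
    return(structure(list(shortlist = tibble(), audit = tibble()),
                     class = "gridock_funnel"))
  }
  stopifnot(all(c("compound", "score") %in% names(d)))
  d$exit_stage <- NA_character_

  s1 <- d$score > thresholds$score_cutoff
  d$exit_stage[s1] <- "stage1_score"
  if ("first_cluster_population" %in% names(d)) {
    s2 <- is.na(d$exit_stage) &
      d$first_cluster_population < thresholds$min_first_cluster
    d$exit_stage[s2] <- "stage2_cluster"
  }
  if ("pockets_occupied" %in% names(d)) {
    s3 <- is.na(d$exit_stage) & !d$pockets_occupied
    d$exit_stage[s3] <- "stage3_pocket"
  }
  surv <- is.na(d$exit_stage)
  if (any(surv)) {
    if (is.null(enthalpy_reports)) {
      abort(sprintf("Missing enthalpy report for compound(s): %s",
                    paste(d$compound[surv], collapse = ", ")))
    }
    e <- as_tibble(enthalpy_reports)
    miss <- setdiff(d$compound[surv], e$compound)
    if (length(miss) > 0) {
      abort(sprintf("Missing enthalpy report for compound(s): %s",
                    paste(miss, collapse = ", ")))
    }
    d <- left_join(d, select(e, "compound", "dH_bind"), by = "compound")
  } else {
    d$dH_bind <- NA_real_
  }
  d$exit_stage[surv] <- "pass"
  shortlist <- d |>
    filter(.data$exit_stage == "pass") |>
    arrange(.data$dH_bind, .data$compound)
  if (is.finite(thresholds$enthalpy_rank_keep) &&
      nrow(shortlist) > thresholds$enthalpy_rank_keep) {
    cut <- shortlist$compound[-seq_len(thresholds$enthalpy_rank_keep)]
    d$exit_stage[d$compound %in% cut] <- "stage4_enthalpy_rank"
    shortlist <- head(shortlist, thresholds$enthalpy_rank_keep)
  }
  shortlist$rank <- seq_len(nrow(shortlist))
  structure(list(shortlist = shortlist,
                 audit = select(d, "compound", "score",
                                dplyr::any_of(c("first_cluster_population",
                                                "pockets_occupied",
                                                "dH_bind")), "exit_stage"),
                 thresholds = thresholds),
            class = "gridock_funnel")
}

#' @export
print.gridock_funnel <- function(x, ...) {
  cat(sprintf("<gridock_funnel> %d compound(s) in, %d shortlisted\n",
              nrow(x$audit), nrow(x$shortlist)))
  if (nrow(x$audit) > 0) {
    tab <- table(x$audit$exit_stage)
    for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' @export
tidy.gridock_funnel <- function(x, ...) x$audit

#' @export
glance.gridock_funnel <- function(x, ...) {
  tibble(n_input = nrow(x$audit), n_shortlist = nrow(x$shortlist),
         score_cutoff = x$thresholds$score_cutoff,
         min_first_cluster = x$thresholds$min_first_cluster)
}

#' Plot the funnel audit
#'
#' @param object A `gridock_funnel`.
#' @param ... Unused.
#' @export
autoplot.gridock_funnel <- function(object, ...) {
  df <- object$audit
  ggplot2::ggplot(df, ggplot2::aes(.data$exit_stage)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "exit stage", y = "compounds",
                  title = "screening funnel audit")
}

# ---- descriptors -------------------------------------------------------------

#' Monoisotopic protonated mass from a molecular formula
#'
#' Sum of most-abundant-isotope masses plus the proton mass (1.007276 Da),
#' the `[M+H]+` value matched against high-resolution mass spectrometry.
#'
#' @param formula Molecular formula string (e.g. `"C27H23N3O5"`) or a named
#'   count vector.
#' @return Monoisotopic `[M+H]+` mass in Da.
#' @examples
#' monoisotopic_mz("C27H23N3O5") # 470.1710
#' @export
monoisotopic_mz <- function(formula) {
  counts <- if (is.character(formula)) .parse_formula(formula) else formula
  unknown <- setdiff(names(counts), names(.isotope_masses))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown element(s) in formula: %s",
                  paste(unknown, collapse = ", ")))
  }
  sum(.isotope_masses[names(counts)] * counts) + .proton_mass
}

.parse_formula <- function(formula) {
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    abort(sprintf("Cannot parse formula '%s'.", formula))
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

#' Compute ADME and identity descriptors
#'
#' Molecular weight, monoisotopic `[M+H]+`, Wildman--Crippen logP and Ertl
#' topological polar surface area (through OpenBabel), Lipinski donor and
#' acceptor counts (OH+NH and N+O), rotatable bonds (acyclic single bonds
#' between non-terminal heavy atoms, amide C-N excluded), Lipinski
#' violations (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10) and the Pfizer
#' 3/75 flag (logP < 3 and TPSA > 75 A^2). logP-dependent values are
#' model-dependent: a different logP model can move compounds across the
#' Lipinski/Pfizer boundaries.
#'
#' @param molecules A character vector of SMILES (optionally named), a list
#'   of `gridock_ligand` objects, or a single `gridock_ligand`.
#' @return A tibble with one row per molecule.
#' @export
compute_descriptors <- function(molecules) {
  if (inherits(molecules, "gridock_ligand")) molecules <- list(molecules)
  if (is.character(molecules)) {
    smiles <- molecules
    names(smiles) <- names(molecules) %||% paste0("mol", seq_along(smiles))
    ligs <- NULL
  } else {
    smiles <- NULL
    ligs <- molecules
  }
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("compute_descriptors requires the ChemmineOB package.")
  }
  if (is.null(smiles)) {
    # export topologies to SDF for the OpenBabel property engine
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    write_ligands(ligs, tmp)
    sdfstr <- paste(readLines(tmp), collapse = "\n")
    props <- ChemmineOB::forEachMol("SDF", sdfstr, ChemmineOB::prop_OB)
    prop <- bind_rows(props)
    nms <- map(ligs, "name")
  } else {
    smi_named <- paste0(smiles, " ", names(smiles))
    props <- lapply(smi_named, function(s) {
      ChemmineOB::forEachMol("SMILES", s, ChemmineOB::prop_OB)[[1]]
    })
    prop <- bind_rows(props)
    sdfstr <- ChemmineOB::convertFormat("SMI", "SDF",
                                        paste(smi_named, collapse = "\n"))
    ligs <- .read_sdf_records_all(sdfstr)
    nms <- as.list(names(smiles))
  }
  rows <- lapply(seq_along(ligs), function(k) {
    lig <- ligs[[k]]
    el <- lig$atoms$element
    adj <- .adjacency(length(el), lig$bonds)
    # Lipinski original definitions
    hbd <- sum(vapply(which(el %in% c("N", "O")), function(i) {
      sum(el[adj[[i]]] == "H")
    }, numeric(1)))
    # OpenBabel SMILES conversions keep hydrogens implicit; recover OH/NH
    # counts from heavy-atom valence when no explicit hydrogens are present
    if (!any(el == "H")) {
      hbd <- sum(vapply(which(el %in% c("N", "O")), function(i) {
        ords <- vapply(seq_len(nrow(lig$bonds)), function(b) {
          if (lig$bonds$i[b] == i || lig$bonds$j[b] == i) {
            if (lig$bonds$order[b] == 4) 1.5 else lig$bonds$order[b]
          } else 0
        }, numeric(1))
        std_val <- if (el[i] == "N") 3 else 2
        max(0, round(std_val + lig$atoms$formal_charge[i] - sum(ords)))
      }, numeric(1)))
    }
    hba <- sum(el %in% c("N", "O"))
    rotb <- nrow(lig$torsions)
    # with implicit hydrogens the atom-table formula lacks H; use the
    # property engine's hydrogen-complete formula instead
    formula <- if (any(el == "H")) format_formula(lig$formula) else
      gsub("[+-]+[0-9]*$", "", as.character(prop$formula[k]))
    mz <- monoisotopic_mz(formula)
    logp <- as.numeric(prop$logP[k])
    tpsa <- as.numeric(prop$TPSA[k])
    mw_avg <- as.numeric(prop$MW[k])
    lip <- sum(mw_avg > 500, logp > 5, hbd > 5, hba > 10)
    tibble(compound = nms[[k]], formula = formula,
           mw = mw_avg, mz_mh = mz, logp = logp, tpsa = tpsa,
           hbd = as.integer(hbd), hba = as.integer(hba),
           rotatable_bonds = as.integer(rotb),
           lipinski_violations = as.integer(lip),
           pfizer_3_75 = logp < 3 & tpsa > 75)
  })
  bind_rows(rows)
}

# parse every record of an SDF string into topologies (no skipping)
.read_sdf_records_all <- function(sdfstr) {
  str <- ChemmineR::read.SDFstr(strsplit(sdfstr, "\n")[[1]])
  lapply(seq_along(str@a), function(k) .sdf_record_to_ligand(str@a[[k]], k))
}

#' The thirteen factor XIIa screening compounds
#'
#' Structures of the thirteen compounds selected for experimental testing,
#' encoded in-house as SMILES from their published names, together with the
#' published molecular formulas and calculated `[M+H]+` values. Useful for
#' descriptor benchmarking.
#'
#' @return A tibble with `compound`, `formula`, `mz_mh_published`, `smiles`.
#' @export
fxiia_compounds <- function() {
  path <- system.file("extdata", "fxiia_compounds.tsv", package = "gridock")
  as_tibble(utils::read.delim(path, colClasses = c("character", "character",
                                                   "numeric", "character")))
}
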