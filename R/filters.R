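#' Default configuration for the structural design filters
#'
#' @param numbering_offset Added to a candidate's sequence position to
#'   obtain the structure's author residue number.
#' @param active_site_cutoff Angstrom; candidates strictly closer than
#'   this to the active site are rejected (exactly at the cutoff passes).
#' @param distance_mode `"atom"` (all-atom minimum) or `"ca"`.
#' @param kd_threshold Kyte–Doolittle value at and above which a residue
#'   counts as hydrophobic.
#' @param surface_threshold,core_threshold Relative-SASA class cutoffs.
#' @param probe_radius,n_points SASA parameters.
#' @param hbond_cutoff,salt_cutoff Interaction-detection cutoffs.
#' @param check_identity Error when the structure's residue type differs
#'   from the candidate's stated wild-type residue.
#' @return Named list of filter settings.
#' @export
filter_config <- function(numbering_offset = 0L, active_site_cutoff = 5.0,
                          distance_mode = "atom", kd_threshold = 0,
                          surface_threshold = 0.25, core_threshold = 0.10,
                          probe_radius = 1.4, n_points = 960L,
                          hbond_cutoff = 3.5, salt_cutoff = 4.0,
                          check_identity = TRUE) {
  as.list(environment())
}

## Can `aa` reproduce the side-chain interactions in `ints` (rows from
## sidechain_interactions_of for the wild-type residue)? Returns a
## character vector describing each interaction the proposal loses.
lost_interactions <- function(ints, wt_aa, proposed_aa, resno) {
  if (!nrow(ints)) return(character(0))
  lost <- character(0)
  for (r in seq_len(nrow(ints))) {
    row <- ints[r, ]
    own_first <- row$resno1 == resno
    partner <- sprintf("%s%d:%s",
                       if (own_first) row$resid2 else row$resid1,
                       if (own_first) row$resno2 else row$resno1,
                       if (own_first) row$atom2 else row$atom1)
    if (row$type == "salt_bridge") {
      wt_pos <- wt_aa %in% SIDECHAIN_POSITIVE
      ok <- if (wt_pos) proposed_aa %in% SIDECHAIN_POSITIVE
            else proposed_aa %in% SIDECHAIN_NEGATIVE
      if (!ok)
        lost <- c(lost, sprintf("salt bridge to %s (%.2f A) needs %s charge",
                                partner, row$distance,
                                if (wt_pos) "positive" else "negative"))
    } else {
      polar <- proposed_aa %in% union(SIDECHAIN_HBOND_DONOR,
                                      SIDECHAIN_HBOND_ACCEPTOR)
      if (!polar)
        lost <- c(lost, sprintf("side-chain H-bond to %s (%.2f A) needs polar side chain",
                                partner, row$distance))
    }
  }
  lost
}

#' Apply the three structural rejection rules to consensus candidates
#'
#' Rule 1 (active-site proximity): reject candidates whose residue lies
#' strictly within `active_site_cutoff` of the user-specified active site
#' — mutating near the catalytic machinery risks activity. Rule 2
#' (hydrophobicity mismatch): reject proposals that would put a
#' hydrophobic residue (Kyte–Doolittle >= threshold) on the surface or a
#' hydrophilic one in the core; intermediate residues pass. Rule 3
#' (interaction loss): reject proposals whose residue type cannot
#' reproduce a side-chain hydrogen bond or salt bridge the wild-type
#' residue currently makes. Every verdict carries the measured evidence.
#'
#' @param candidates Data frame from [candidate_positions()] (columns
#'   `target_position`, `target_aa`, `consensus_aa`, `frequency`).
#' @param model A `structure_model`.
#' @param site An [active_site()] object.
#' @param config A [filter_config()] list.
#' @return Data frame of class `mutation_candidates`: one row per
#'   candidate with `mutation`, `target_position`, `wt_aa`,
#'   `proposed_aa`, `consensus_frequency`, `min_active_site_distance`,
#'   `relative_sasa`, `location_class`, `n_sidechain_interactions`,
#'   `verdict`, `rejection_rules` (`;`-joined), `evidence`.
#' @export
apply_design_filters <- function(candidates, model, site,
                                 config = filter_config()) {
  stopifnot(inherits(model, "structure_model"), inherits(site, "active_site"))
  need <- c("target_position", "target_aa", "consensus_aa", "frequency")
  if (!all(need %in% names(candidates)))
    stop("candidates must have columns: ", paste(need, collapse = ", "))

  resnos <- candidates$target_position + config$numbering_offset
  present <- resnos %in% model$resno[!model$het]
  if (!all(present))
    stop("candidate positions not mappable to the structure: ",
         paste(candidates$target_position[!present], collapse = ", "))

  sasa <- shrake_rupley_sasa(model, probe_radius = config$probe_radius,
                             n_points = config$n_points)
  ints <- detect_interactions(model, hbond_cutoff = config$hbond_cutoff,
                              salt_cutoff = config$salt_cutoff)

  out <- lapply(seq_len(nrow(candidates)), function(i) {
    pos <- candidates$target_position[i]
    resno <- resnos[i]
    wt <- candidates$target_aa[i]
    prop <- candidates$consensus_aa[i]
    struct_resid <- model$resid[!model$het & model$resno == resno][1]
    if (config$check_identity && !is.na(AA_ONE[struct_resid]) &&
        AA_ONE[[struct_resid]] != wt)
      stop("structure residue ", resno, " is ", struct_resid,
           " but candidate wild type is ", wt,
           "; check the numbering offset")

    rules <- character(0)
    evidence <- character(0)

    dmin <- min_distance_to_active_site(model, resno, site,
                                        mode = config$distance_mode)
    if (dmin < config$active_site_cutoff) {
      rules <- c(rules, "active_site_proximity")
      evidence <- c(evidence, sprintf("min distance to active site %.2f A < %.1f A",
                                      dmin, config$active_site_cutoff))
    }

    rs <- sasa$residue_sasa
    res_sasa <- rs$sasa[rs$resno == resno][1]
    loc <- classify_location(res_sasa, struct_resid,
                             surface_threshold = config$surface_threshold,
                             core_threshold = config$core_threshold)
    kd <- KYTE_DOOLITTLE[[prop]]
    hydrophobic <- kd >= config$kd_threshold
    if (hydrophobic && loc$location_class == "surface") {
      rules <- c(rules, "hydrophobicity_mismatch")
      evidence <- c(evidence, sprintf(
        "proposed %s is hydrophobic (KD %.1f) at surface position (rel. SASA %.2f)",
        prop, kd, loc$relative_sasa))
    } else if (!hydrophobic && loc$location_class == "core") {
      rules <- c(rules, "hydrophobicity_mismatch")
      evidence <- c(evidence, sprintf(
        "proposed %s is hydrophilic (KD %.1f) at core position (rel. SASA %.2f)",
        prop, kd, loc$relative_sasa))
    }

    own <- sidechain_interactions_of(ints, resno)
    lost <- lost_interactions(own, wt, prop, resno)
    if (length(lost)) {
      rules <- c(rules, "interaction_loss")
      evidence <- c(evidence, lost)
    }

    data.frame(
      mutation = paste0(wt, pos, prop), target_position = pos,
      wt_aa = wt, proposed_aa = prop,
      consensus_frequency = candidates$frequency[i],
      min_active_site_distance = dmin,
      relative_sasa = loc$relative_sasa, location_class = loc$location_class,
      n_sidechain_interactions = nrow(own),
      verdict = if (length(rules)) "rejected" else "accepted",
      rejection_rules = paste(rules, collapse = ";"),
      evidence = paste(evidence, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  verdicts <- do.call(rbind, out)
  rownames(verdicts) <- NULL
  class(verdicts) <- c("mutation_candidates", "data.frame")
  verdicts
}

#' Write a filter report
#'
#' @param verdicts An [apply_design_filters()] result.
#' @param path Output path; `.json` extension switches to JSON.
#' @export
write_filter_report <- function(verdicts, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(verdicts, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
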