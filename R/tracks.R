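#' Per-residue structural feature tracks for a mutated site
#'
#' Combines the component computations into one aligned per-residue
#' table, mirroring the track stack of an interactive protein feature
#' view: solvent accessibility (ASA and RSA), C-alpha distance to the
#' mutated residue, three-state secondary structure, protein-domain
#' membership (from an input interval table), optional precomputed
#' binding-site probabilities, and nearby known variants.
#'
#' A rule-based one-line interpretation of the mutated site's context is
#' attached as the `"context_summary"` attribute (see
#' [context_summary()]).
#'
#' @param structure A [read_structure()] result.
#' @param mutated_index Residue index of the mutated site.
#' @param domain_table Optional tibble (`start`, `end`, `label`), 1-based
#'   inclusive residue intervals.
#' @param known_variants Optional tibble (`aa_pos`, `label`).
#' @param binding_table Optional tibble (`res_index`, `binding_prob`) of
#'   precomputed binding-site probabilities.
#' @param predictor_score Optional pathogenicity predictor score in
#'   \[0, 1\] for the mutated variant, used only by the context summary.
#' @param probe_radius,n_points Shrake-Rupley parameters, see
#'   [compute_asa()].
#' @return Tibble of class `residue_features`: `res_index`, `aa`, `asa`,
#'   `rsa`, `calpha_dist`, `ss`, `domain`, `binding_prob`,
#'   `known_variant`, `confidence`.
#' @export
build_feature_tracks <- function(structure, mutated_index,
                                 domain_table = NULL, known_variants = NULL,
                                 binding_table = NULL,
                                 predictor_score = NA_real_,
                                 probe_radius = 1.4, n_points = 960) {
  res <- structure$residues
  rng <- range(res$res_index)
  check_track <- function(tab, cols, name) {
    if (is.null(tab)) return(NULL)
    tab <- as_tibble(tab)
    missing <- setdiff(cols, colnames(tab))
    if (length(missing) > 0) {
      otr_error(paste0("track '", name, "' is missing column(s): ",
                       paste(missing, collapse = ", ")),
                "oncotherapyr_track_error")
    }
    tab
  }
  domain_table <- check_track(domain_table, c("start", "end", "label"),
                              "domains")
  known_variants <- check_track(known_variants, c("aa_pos", "label"),
                                "known_variants")
  binding_table <- check_track(binding_table, c("res_index", "binding_prob"),
                               "binding_sites")
  if (!is.null(binding_table) &&
      !all(binding_table$res_index %in% res$res_index)) {
    otr_error("track 'binding_sites' refers to residues not in the structure",
              "oncotherapyr_track_error")
  }

  feats <- compute_rsa(compute_asa(structure, probe_radius, n_points)) |>
    left_join(calpha_distances(structure, mutated_index)[
      c("res_index", "calpha_dist")], by = "res_index") |>
    left_join(assign_secondary_structure(structure)[c("res_index", "ss")],
              by = "res_index")

  feats$domain <- NA_character_
  if (!is.null(domain_table)) {
    for (k in seq_len(nrow(domain_table))) {
      inside <- feats$res_index >= domain_table$start[k] &
        feats$res_index <= domain_table$end[k]
      feats$domain[inside] <- domain_table$label[k]
    }
  }
  feats$binding_prob <- if (is.null(binding_table)) NA_real_ else
    binding_table$binding_prob[match(feats$res_index, binding_table$res_index)]
  feats$known_variant <- if (is.null(known_variants)) NA_character_ else
    known_variants$label[match(feats$res_index, known_variants$aa_pos)]
  feats$confidence <- res$confidence[match(feats$res_index, res$res_index)]

  out <- structure(feats, class = c("residue_features", class(feats)))
  attr(out, "mutated_index") <- mutated_index
  attr(out, "context_summary") <- context_summary(out, mutated_index,
                                                  predictor_score)
  out
}

#' Rule-based interpretation of a mutated site's structural context
#'
#' Encodes the interpretation pattern used when reading feature tracks by
#' eye: a residue inside an annotated domain, buried (RSA below the
#' protein average), with a high predictor score reads as a
#' pathogenic-leaning context; a loop residue outside any domain with
#' above-average RSA and a low predictor score as benign-leaning;
#' everything else is indeterminate. Average RSA is the unweighted mean
#' over residues with computed ASA.
#'
#' @param features A [build_feature_tracks()] table (or compatible tibble
#'   with `res_index`, `rsa`, `ss`, `domain`).
#' @param mutated_index Residue index of the mutated site.
#' @param predictor_score Predictor score in \[0, 1\] or `NA`.
#' @return One-line character summary tagged `pathogenic-leaning
#'   context`, `benign-leaning context`, or `indeterminate context`.
#' @export
context_summary <- function(features, mutated_index,
                            predictor_score = NA_real_) {
  row <- features[features$res_index == mutated_index, , drop = FALSE]
  if (nrow(row) == 0) return("indeterminate context: mutated residue absent")
  mean_rsa <- mean(features$rsa, na.rm = TRUE)
  in_domain <- !is.na(row$domain)
  buried <- !is.na(row$rsa) && row$rsa < mean_rsa
  high_pred <- !is.na(predictor_score) && predictor_score >= 0.5
  low_pred <- !is.na(predictor_score) && predictor_score < 0.5
  loop <- !is.na(row$ss) && row$ss == "C"

  desc <- paste0("residue ", mutated_index, " (", row$aa, "): ",
                 if (in_domain) paste0("in domain '", row$domain, "'")
                 else "outside annotated domains",
                 ", ", switch(row$ss, H = "alpha helix", E = "beta strand",
                              "loop"),
                 ", RSA ", sprintf("%.2f", row$rsa),
                 if (buried) " (below protein average)"
                 else " (above protein average)")
  tag <- if (in_domain && buried && high_pred) {
    "pathogenic-leaning context"
  } else if (!in_domain && loop && !buried && low_pred) {
    "benign-leaning context"
  } else {
    "indeterminate context"
  }
  paste0(desc, " -> ", tag)
}

#' Export per-residue feature tracks
#'
#' @param features A [build_feature_tracks()] table.
#' @param path Output path; `.json` gives nested JSON, anything else TSV
#'   with columns index, aa, asa, rsa, calpha_dist, ss, domain,
#'   binding_prob.
#' @return The output path, invisibly.
#' @export
write_feature_tracks <- function(features, path) {
  flat <- tibble(index = features$res_index, aa = features$aa,
                 asa = round(features$asa, 2), rsa = round(features$rsa, 3),
                 calpha_dist = round(features$calpha_dist, 2),
                 ss = features$ss, domain = features$domain,
                 binding_prob = features$binding_prob)
  if (grepl("\\.json$", path)) {
    payload <- list(mutated_index = attr(features, "mutated_index"),
                    context_summary = attr(features, "context_summary"),
                    residues = flat)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                                na = "null"), path)
  } else {
    readr::write_tsv(flat, path, progress = FALSE)
  }
  invisible(path)
}

#' Track-stack plot of per-residue features
#'
#' Draws the classic multi-track view: RSA and C-alpha distance profiles,
#' secondary-structure and domain ribbons, and known-variant marks, with
#' the mutated site highlighted.
#'
#' @param object A `residue_features` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_features <- function(object, ...) {
  mut <- attr(object, "mutated_index")
  long <- bind_rows(
    tibble(res_index = object$res_index, track = "RSA", value = object$rsa),
    tibble(res_index = object$res_index, track = "C-alpha distance (A)",
           value = object$calpha_dist)
  )
  ribbon <- tibble(res_index = object$res_index,
                   ss = object$ss, domain = object$domain)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$res_index, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = mut, colour = "red",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue", y = NULL,
                  title = "Per-residue structural context",
                  subtitle = attr(object, "context_summary")) +
    ggplot2::theme_minimal()
}
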