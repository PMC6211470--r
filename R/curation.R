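#' Curation configuration
#'
#' Tunable knobs of the rule engine, with the defaults used throughout.
#'
#' @param end_slack Terminal-boundary tolerance (bp) when deciding that two
#'   models share the same gene structure. Default 0.
#' @param min_reciprocal Reciprocal exonic-overlap threshold used wherever
#'   single-exon structures are matched. Default 0.9.
#' @param addition_rule `"conjunctive"` (default) requires a novel exon to be
#'   backed by (one transcript evidence AND one annotation of another
#'   source/species) OR two transcript evidences; `"any"` accepts a single
#'   backer of either kind.
#' @param isoform_overlap Span-overlap fraction (of the shorter span) above
#'   which co-located models are merged as isoforms. Default 0.7 (strict
#'   `>`).
#' @param count_protein Count protein alignments as independent evidence.
#' @param support_threshold Coverage fraction at which an evidence class
#'   supports a model. Default 0.7.
#' @param stranded Strand-aware overlap computations. Default `TRUE`.
#' @param keep_level4 Retain level-4 (single-evidence) models in the curated
#'   output. Default `FALSE`.
#' @return A named list of settings.
#' @export
curation_config <- function(end_slack = 0L, min_reciprocal = 0.9,
                            addition_rule = c("conjunctive", "any"),
                            isoform_overlap = 0.7, count_protein = FALSE,
                            support_threshold = 0.7, stranded = TRUE,
                            keep_level4 = FALSE) {
  list(end_slack = as.integer(end_slack), min_reciprocal = min_reciprocal,
       addition_rule = match.arg(addition_rule),
       isoform_overlap = isoform_overlap, count_protein = count_protein,
       support_threshold = support_threshold, stranded = stranded,
       keep_level4 = keep_level4)
}

TRANSCRIPT_EVIDENCE <- c("cDNA", "EST", "RNAseq_high_confidence")

## internal: evidence/model rows overlapping a single-transcript table's span
overlapping_rows <- function(pool, tx, stranded = TRUE) {
  if (nrow(pool) == 0) return(pool)
  keep <- pool$chrom == tx$chrom[1] & pool$start < max(tx$end) &
    pool$end > min(tx$start)
  if (stranded) keep <- keep & strand_compatible(pool$strand, tx$strand[1])
  pool[keep, ]
}

## internal: alignments (as single-transcript tables) overlapping tx's span
overlapping_models <- function(pool, tx, stranded = TRUE) {
  hits <- overlapping_rows(pool, tx, stranded)
  if (nrow(hits) == 0) return(list())
  split_models(pool[pool$transcript_id %in% hits$transcript_id, ])
}

## internal: does alignment `al` support candidate structure `tx`?
## identical intron chain for multi-exon, reciprocal overlap for single-exon.
supports_structure <- function(tx, al, min_reciprocal = 0.9,
                               stranded = TRUE) {
  if (stranded && !strand_compatible(tx$strand[1], al$strand[1])) return(FALSE)
  if (tx$chrom[1] != al$chrom[1]) return(FALSE)
  if (nrow(tx) > 1) {
    chain_of(tx) == chain_of(al)
  } else {
    reciprocal_overlap(tx, al, stranded = stranded) >= min_reciprocal
  }
}

## internal: number of transcript-evidence alignments matching tx's
## structure, plus tie-break metadata (best priority among supporters)
structure_support <- function(tx, evidence, cfg) {
  ev <- evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ]
  als <- overlapping_models(ev, tx, cfg$stranded)
  n <- 0L
  best_priority <- Inf
  ids <- character()
  for (al in als) {
    if (supports_structure(tx, al, cfg$min_reciprocal, cfg$stranded)) {
      n <- n + 1L
      ids <- c(ids, al$transcript_id[1])
      best_priority <- min(best_priority,
                           EVIDENCE_PRIORITY[[al$evidence_class[1]]])
    }
  }
  list(n = n, best_priority = best_priority, ids = ids)
}

## internal: rebuild a single-transcript table from exon coordinates
rebuild_model <- function(template, starts, ends) {
  ord <- order(starts)
  tibble(transcript_id = template$transcript_id[1],
         gene_id = template$gene_id[1], chrom = template$chrom[1],
         start = as.integer(starts[ord]), end = as.integer(ends[ord]),
         strand = template$strand[1], source = template$source[1])
}

## internal: exon union of several single-transcript tables
exon_union <- function(models_list, template = models_list[[1]]) {
  allx <- bind_rows(models_list)
  ir <- IRanges::reduce(IRanges::IRanges(allx$start + 1L, allx$end))
  rebuild_model(template, IRanges::start(ir) - 1L, IRanges::end(ir))
}

#' Extend a model's terminal exons to the longest supported ends
#'
#' Among the model itself and all candidates compatible with it at the
#' termini (identical intron chain for multi-exon models; any overlapping
#' alignment for single-exon models), the outermost 5' and 3' coordinates
#' replace the terminal exon boundaries. Internal structure is untouched; a
#' model with no compatible candidate is returned unchanged. On the minus
#' strand the biological 5' end is the highest genomic coordinate, but since
#' both ends take their outermost supported coordinate the arithmetic is
#' strand-symmetric.
#'
#' @param model A single-transcript gene model tibble.
#' @param candidates A gene model/evidence tibble of candidate end donors.
#' @param cfg A [curation_config()].
#' @return The (possibly extended) model.
#' @export
adjust_terminal_ends <- function(model, candidates,
                                 cfg = curation_config()) {
  model <- model[order(model$start), ]
  new_start <- min(model$start)
  new_end <- max(model$end)
  for (cand in overlapping_models(candidates, model, cfg$stranded)) {
    compatible <- if (nrow(model) > 1) {
      chain_of(cand) == chain_of(model)
    } else {
      exonic_overlap(model, cand, stranded = cfg$stranded) > 0
    }
    if (compatible) {
      new_start <- min(new_start, min(cand$start))
      new_end <- max(new_end, max(cand$end))
    }
  }
  starts <- model$start
  ends <- model$end
  starts[1] <- new_start
  ends[nrow(model)] <- new_end
  rebuild_model(model, starts, ends)
}

outcome <- function(model_id, level, action, result, rules,
                    evidence_ids = character()) {
  list(model_id = model_id, level = level, action = action, result = result,
       rules = rules, evidence_ids = evidence_ids)
}

#' Curate a highest-confidence (level 1) gene model
#'
#' Level-1 models are reconciled with their matched reference (RefSeq)
#' model: identical structures are kept as-is (rule 1.1); models differing
#' only at the terminal ends take the longest supported ends (1.2);
#' genuinely different structures are resolved in favour of whichever
#' candidate — the model or the reference — is matched by more evidence
#' alignments, falling back to the reference when neither has support (1.3);
#' multiple overlapping reference models are first merged when they are
#' transcripts of one gene, otherwise the most-evidenced one is used (1.4).
#'
#' @param model Single-transcript gene model tibble, assigned level 1.
#' @param refseq Reference annotation tibble.
#' @param evidence Evidence tibble (high-confidence RNA-seq pre-filtered).
#' @param cfg A [curation_config()].
#' @return A curation outcome (internal list; see [run_curation()]).
#' @export
curate_level1 <- function(model, refseq, evidence, cfg = curation_config()) {
  model <- model[order(model$start), ]
  rules <- character()
  matches <- overlapping_models(refseq, model, cfg$stranded)
  if (length(matches) == 0) {
    return(outcome(model$transcript_id[1], 1L, "kept_identical", model,
                   "1.0-no-refseq-match"))
  }
  if (length(matches) > 1) {
    rules <- c(rules, "1.4")
    gids <- vapply(matches, function(m) m$gene_id[1], character(1))
    if (length(unique(gids)) == 1) {
      rs <- exon_union(matches)
    } else {
      supp <- vapply(matches, function(m) structure_support(m, evidence, cfg)$n,
                     integer(1))
      best <- order(-supp, vapply(matches, function(m) m$transcript_id[1],
                                  character(1)))[1]
      rs <- matches[[best]]
    }
  } else {
    rs <- matches[[1]]
  }

  if (same_structure(model, rs, cfg$end_slack)) {
    return(outcome(model$transcript_id[1], 1L, "kept_identical", model,
                   c(rules, "1.1"), rs$transcript_id[1]))
  }
  same_chain <- chain_of(model) == chain_of(rs)
  if (same_chain) {
    donors <- bind_rows(
      rs, evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ])
    adj <- adjust_terminal_ends(model, donors, cfg)
    return(outcome(model$transcript_id[1], 1L, "end_adjusted", adj,
                   c(rules, "1.2"), rs$transcript_id[1]))
  }
  ## rule 1.3: pick the structure with the most evidence alignments
  sm <- structure_support(model, evidence, cfg)
  sr <- structure_support(rs, evidence, cfg)
  pick_model <-
    sm$n > sr$n ||
    (sm$n == sr$n && sm$n > 0 &&
       (sm$best_priority < sr$best_priority ||
          (sm$best_priority == sr$best_priority &&
             sum(model$end - model$start) >= sum(rs$end - rs$start))))
  if (pick_model) {
    outcome(model$transcript_id[1], 1L, "kept_identical", model,
            c(rules, "1.3"), sm$ids)
  } else {
    res <- rebuild_model(model, rs$start, rs$end)
    outcome(model$transcript_id[1], 1L, "structure_replaced", res,
            c(rules, if (sm$n == 0 && sr$n == 0) "1.3-refseq-fallback"
              else "1.3"),
            c(rs$transcript_id[1], sr$ids))
  }
}

## internal: merge introns that every evidence class present treats as
## exonic; returns list(model, merged = logical)
merge_supported_introns <- function(model, evidence, cfg) {
  model <- model[order(model$start), ]
  merged_any <- FALSE
  ev <- evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ]
  repeat {
    if (nrow(model) < 2) break
    near <- overlapping_rows(ev, model, cfg$stranded)
    done <- TRUE
    for (k in seq_len(nrow(model) - 1)) {
      i_start <- model$end[k]
      i_end <- model$start[k + 1]
      present <- unique(near$evidence_class)
      if (length(present) == 0) next
      agree <- vapply(present, function(cl) {
        rows <- near[near$evidence_class == cl, ]
        any(rows$start <= i_start & rows$end >= i_end)
      }, logical(1))
      if (all(agree)) {
        starts <- model$start[-(k + 1)]
        ends <- model$end[-k]
        model <- rebuild_model(model, starts, ends)
        merged_any <- TRUE
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  list(model = model, merged = merged_any)
}

#' Curate a reference-only (level 2) gene model
#'
#' Level-2 models have no transcriptional support beyond the reference
#' annotation. Duplicated gene ids collapse onto the model flagged as the
#' best reference transcript (rule 2.1); unsupported single-exon models are
#' deleted (2.2); introns that every evidence class present treats as exonic
#' are merged, and a multi-exon model that any present class contradicts is
#' handed to the level-3 structural rules (2.3).
#'
#' @param model Single-transcript gene model tibble, assigned level 2.
#' @param siblings Other level-2 models sharing annotation (for rule 2.1).
#' @param evidence Evidence tibble.
#' @param ncbi,other_refseq Independent annotation tibbles, consulted when
#'   level-3 rules are invoked.
#' @param cfg A [curation_config()].
#' @param refseq Reference annotation tibble; matched reference models also
#'   serve as terminal-end donors when the structural rules are invoked.
#' @return A curation outcome.
#' @export
curate_level2 <- function(model, siblings, evidence,
                          ncbi = empty_models(),
                          other_refseq = empty_models(),
                          cfg = curation_config(),
                          refseq = empty_models()) {
  model <- model[order(model$start), ]
  id <- model$transcript_id[1]
  flagged <- function(m) isTRUE(m$best_refseq[1])
  dup <- filter(siblings, .data$gene_id == model$gene_id[1],
                .data$transcript_id != id)
  if (nrow(dup) > 0) {
    sib_flagged <- any(vapply(split_models(dup), flagged, logical(1)))
    if (!flagged(model) && sib_flagged) {
      return(outcome(id, 2L, "deleted", NULL, "2.1"))
    }
  }
  if (nrow(model) == 1) {
    ov <- overlapping_rows(evidence, model, cfg$stranded)
    if (nrow(ov) == 0) {
      return(outcome(id, 2L, "deleted", NULL, "2.2"))
    }
    return(outcome(id, 2L, "kept_identical", model, "2.2",
                   unique(ov$transcript_id)))
  }
  m <- merge_supported_introns(model, evidence, cfg)
  rules <- if (m$merged) "2.3-merge" else character()
  model <- m$model
  ## concordance check: every evidence class present must contain at least
  ## one alignment matching the model structure
  ev <- evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ]
  near <- overlapping_rows(ev, model, cfg$stranded)
  present <- unique(near$evidence_class)
  concordant <- vapply(present, function(cl) {
    als <- split_models(ev[ev$transcript_id %in%
                             near$transcript_id[near$evidence_class == cl], ])
    any(vapply(als, function(al)
      supports_structure(model, al, cfg$min_reciprocal, cfg$stranded),
      logical(1)))
  }, logical(1))
  if (length(present) == 0 || all(concordant)) {
    return(outcome(id, 2L, if (m$merged) "merged" else "kept_identical",
                   model, c(rules, "2.3"), unique(near$transcript_id)))
  }
  out <- curate_level3(model, evidence, ncbi, other_refseq, cfg,
                       .level = 2L, .isoform_stage = FALSE,
                       .end_donors = overlapping_rows(refseq, model,
                                                      cfg$stranded))
  out$rules <- c(rules, "2.3-escalated", out$rules)
  out
}

## internal: cluster candidate novel exons by reciprocal overlap and decide
## additions per the configured rule
candidate_additions <- function(model, evidence, ncbi, other_refseq, cfg) {
  model <- model[order(model$start), ]
  if (nrow(model) < 2) return(NULL)
  tx_ev <- evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ]
  anno <- bind_rows(
    mutate(ncbi, evidence_class = "NCBI"),
    mutate(other_refseq, evidence_class = "other_species_refseq"))
  pool <- bind_rows(overlapping_rows(tx_ev, model, cfg$stranded),
                    overlapping_rows(anno, model, cfg$stranded))
  if (nrow(pool) == 0) return(NULL)
  added <- list()
  for (k in seq_len(nrow(model) - 1)) {
    i_start <- model$end[k]
    i_end <- model$start[k + 1]
    cand <- pool[pool$start >= i_start & pool$end <= i_end, ]
    if (nrow(cand) == 0) next
    cand <- cand[order(cand$start, cand$end), ]
    used <- rep(FALSE, nrow(cand))
    for (a in seq_len(nrow(cand))) {
      if (used[a]) next
      grp <- a
      for (b in seq_len(nrow(cand))) {
        if (b == a || used[b]) next
        ov <- max(0, min(cand$end[a], cand$end[b]) -
                    max(cand$start[a], cand$start[b]))
        la <- cand$end[a] - cand$start[a]
        lb <- cand$end[b] - cand$start[b]
        if (min(ov / la, ov / lb) >= cfg$min_reciprocal) grp <- c(grp, b)
      }
      used[grp] <- TRUE
      sub <- cand[grp, ]
      n_tx <- dplyr::n_distinct(
        sub$transcript_id[sub$evidence_class %in% TRANSCRIPT_EVIDENCE])
      n_anno <- dplyr::n_distinct(
        sub$transcript_id[!sub$evidence_class %in% TRANSCRIPT_EVIDENCE])
      ok <- if (cfg$addition_rule == "conjunctive") {
        (n_tx >= 1 && n_anno >= 1) || n_tx >= 2
      } else {
        n_tx + n_anno >= 1
      }
      if (ok) {
        rep_row <- sub |>
          mutate(prio = EVIDENCE_PRIORITY[.data$evidence_class],
                 len = .data$end - .data$start) |>
          arrange(.data$prio, dplyr::desc(.data$len), .data$start) |>
          dplyr::slice(1)
        added[[length(added) + 1]] <-
          list(start = rep_row$start, end = rep_row$end,
               ids = unique(sub$transcript_id))
      }
    }
  }
  if (length(added) == 0) NULL else added
}

#' Curate a novel (level 3) gene model
#'
#' Level-3 models are absent from the reference annotation and are shaped by
#' the evidence directly, in a fixed order: a structure contradicted by all
#' overlapping cDNAs is replaced by the longest cDNA backed by other
#' evidence (rule 3.4); introns/junctions are merged or the model split when
#' every evidence class present agrees (3.5); novel exons backed by the
#' configured combination of evidences are added (3.2); exons with no
#' biological evidence are deleted (3.3); terminal ends are re-adjusted to
#' the longest supported coordinates (3.1). Isoform merging (3.6) happens
#' across models inside [run_curation()].
#'
#' @param model Single-transcript gene model tibble, assigned level 3.
#' @param evidence Evidence tibble.
#' @param ncbi,other_refseq Annotation tibbles from an independent source and
#'   from other species, used by the exon-addition rule.
#' @param cfg A [curation_config()].
#' @param .level,.isoform_stage,.end_donors Internal.
#' @return A curation outcome (possibly with several result models after a
#'   split).
#' @export
curate_level3 <- function(model, evidence, ncbi = empty_models(),
                          other_refseq = empty_models(),
                          cfg = curation_config(), .level = 3L,
                          .isoform_stage = TRUE,
                          .end_donors = empty_models()) {
  model <- model[order(model$start), ]
  id <- model$transcript_id[1]
  rules <- character()
  ev_ids <- character()
  action <- "kept_identical"

  ## 3.4 structure replacement by cDNA
  cdnas <- overlapping_models(
    evidence[evidence$evidence_class == "cDNA", ], model, cfg$stranded)
  if (length(cdnas) > 0) {
    agree <- vapply(cdnas, function(al)
      supports_structure(model, al, cfg$min_reciprocal, cfg$stranded),
      logical(1))
    if (!any(agree)) {
      other_ev <- evidence[evidence$evidence_class %in%
                             c("EST", "RNAseq_high_confidence"), ]
      backed <- Filter(function(cd) {
        als <- overlapping_models(other_ev, cd, cfg$stranded)
        any(vapply(als, function(al)
          supports_structure(cd, al, cfg$min_reciprocal, cfg$stranded),
          logical(1)))
      }, cdnas)
      if (length(backed) > 0) {
        lens <- vapply(backed, function(cd) sum(cd$end - cd$start), numeric(1))
        ids <- vapply(backed, function(cd) cd$transcript_id[1], character(1))
        best <- backed[[order(-lens, ids)[1]]]
        model <- rebuild_model(model, best$start, best$end)
        rules <- c(rules, "3.4")
        ev_ids <- c(ev_ids, best$transcript_id[1])
        action <- "structure_replaced"
      }
    }
  }

  ## 3.5 mergence (all present classes agree that an intron is exonic)
  m <- merge_supported_introns(model, evidence, cfg)
  if (m$merged) {
    model <- m$model
    rules <- c(rules, "3.5-merge")
    if (action == "kept_identical") action <- "merged"
  }

  ## 3.5 separation: split at an intron that no evidence alignment crosses
  ## while both flanks carry evidence
  result_models <- list(model)
  if (nrow(model) > 1) {
    near <- overlapping_rows(
      evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ],
      model, cfg$stranded)
    if (nrow(near) > 0) {
      f <- factor(near$transcript_id)
      spans <- tibble(
        a = vapply(split(near$start, f), min, numeric(1)),
        b = vapply(split(near$end, f), max, numeric(1)))
      for (k in seq_len(nrow(model) - 1)) {
        left_end <- model$end[k]
        right_start <- model$start[k + 1]
        crosses <- any(spans$a < left_end & spans$b > right_start)
        left_cov <- any(spans$b > model$start[k] & spans$a < left_end)
        right_cov <- any(spans$a < model$end[k + 1] & spans$b > right_start)
        if (!crosses && left_cov && right_cov) {
          p1 <- rebuild_model(model, model$start[1:k], model$end[1:k])
          p1$transcript_id <- paste0(id, "_p1")
          p2 <- rebuild_model(model, model$start[(k + 1):nrow(model)],
                              model$end[(k + 1):nrow(model)])
          p2$transcript_id <- paste0(id, "_p2")
          result_models <- list(p1, p2)
          rules <- c(rules, "3.5-split")
          action <- "split"
          break
        }
      }
    }
  }

  out_models <- list()
  for (part in result_models) {
    ## 3.2 exon addition
    adds <- candidate_additions(part, evidence, ncbi, other_refseq, cfg)
    if (!is.null(adds)) {
      starts <- c(part$start, vapply(adds, `[[`, numeric(1), "start"))
      ends <- c(part$end, vapply(adds, `[[`, numeric(1), "end"))
      part <- rebuild_model(part, starts, ends)
      rules <- c(rules, "3.2")
      ev_ids <- c(ev_ids, unlist(lapply(adds, `[[`, "ids")))
      if (action == "kept_identical") action <- "exons_added"
    }
    ## 3.3 exon deletion: drop exons without any overlapping evidence
    anno <- bind_rows(
      evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE, ],
      mutate(ncbi, evidence_class = "NCBI"),
      mutate(other_refseq, evidence_class = "other_species_refseq"))
    near <- overlapping_rows(anno, part, cfg$stranded)
    supported <- vapply(seq_len(nrow(part)), function(k) {
      any(near$start < part$end[k] & near$end > part$start[k])
    }, logical(1))
    if (!all(supported)) {
      rules <- c(rules, "3.3")
      if (!any(supported)) {
        next  # whole model unsupported: drop this part
      }
      part <- rebuild_model(part, part$start[supported], part$end[supported])
      if (action %in% c("kept_identical", "exons_added")) {
        action <- "exons_deleted"
      }
    }
    ## 3.1 terminal ends
    donors <- bind_rows(
      evidence[evidence$evidence_class %in% TRANSCRIPT_EVIDENCE,
               c("transcript_id", "gene_id", "chrom", "start", "end",
                 "strand", "source")],
      .end_donors[, c("transcript_id", "gene_id", "chrom", "start", "end",
                      "strand", "source")])
    adj <- adjust_terminal_ends(part, donors, cfg)
    if (!identical(adj[c("start", "end")], part[c("start", "end")])) {
      rules <- c(rules, "3.1")
      if (action == "kept_identical") action <- "end_adjusted"
    }
    out_models[[length(out_models) + 1]] <- adj
  }
  if (length(out_models) == 0) {
    return(outcome(id, .level, "deleted", NULL, unique(c(rules, "3.3"))))
  }
  res <- bind_rows(out_models)
  outcome(id, .level, action, res, unique(rules), unique(ev_ids))
}

#' Run the full curation workflow over an annotation
#'
#' Computes support profiles, assigns the four confidence levels, dispatches
#' every model to its level's rule set, merges co-located level-3 survivors
#' whose spans overlap by more than the isoform threshold, and returns the
#' curated annotation with a per-model audit trail. Level-4 (single
#' evidence) and unsupported models are excluded from the output unless
#' `cfg$keep_level4` is set. The whole procedure is deterministic: models
#' are visited in (chrom, span start, id) order and identical inputs yield
#' identical outputs.
#'
#' @param annotation Candidate gene model tibble to curate.
#' @param refseq Reference (RefSeq-like) annotation tibble.
#' @param evidence Evidence tibble; raw `RNAseq` rows are first passed
#'   through [filter_high_confidence_rnaseq()].
#' @param ncbi,other_refseq Independent annotation tibbles (may be empty).
#' @param cfg A [curation_config()].
#' @return An object of class `curation`: a list with `curated` (gene model
#'   tibble), `audit` (one row per input model: `model_id`, `level`,
#'   `action`, `rules_fired`, `evidence_ids`, `n_result`) and `profiles`
#'   (the support/level table). Use [tidy.curation()] / [glance.curation()].
#' @export
run_curation <- function(annotation, refseq, evidence,
                         ncbi = empty_models(),
                         other_refseq = empty_models(),
                         cfg = curation_config()) {
  validate_gene_models(annotation)
  validate_gene_models(refseq)
  validate_evidence(evidence)

  raw_rna <- filter(evidence, .data$evidence_class == "RNAseq")
  if (nrow(raw_rna) > 0) {
    evidence <- bind_rows(
      filter(evidence, .data$evidence_class != "RNAseq"),
      filter_high_confidence_rnaseq(raw_rna,
                                    min_reciprocal = cfg$min_reciprocal,
                                    stranded = cfg$stranded))
  }

  support_view <- bind_rows(
    evidence,
    mutate(refseq, evidence_class = "RefSeq", tissue = NA_character_),
    if (nrow(ncbi) > 0) mutate(ncbi, evidence_class = "NCBI",
                               tissue = NA_character_),
    if (nrow(other_refseq) > 0)
      mutate(other_refseq, evidence_class = "other_species_refseq",
             tissue = NA_character_))
  profiles <- compute_support(annotation, support_view,
                              support_threshold = cfg$support_threshold,
                              count_protein = cfg$count_protein,
                              stranded = cfg$stranded)
  profiles <- assign_confidence_level(profiles, cfg$support_threshold)
  lvl <- setNames(profiles$level, profiles$model_id)

  models <- split_models(annotation)
  level2_ids <- names(lvl)[!is.na(lvl) & lvl == 2L]
  level2_models <- filter(annotation, .data$transcript_id %in% level2_ids)

  outcomes <- list()
  for (tx in models) {
    id <- tx$transcript_id[1]
    level <- lvl[[id]]
    oc <- if (is.na(level)) {
      outcome(id, NA_integer_, "deleted", NULL, "unsupported")
    } else if (level == 1L) {
      curate_level1(tx, refseq, evidence, cfg)
    } else if (level == 2L) {
      curate_level2(tx, level2_models, evidence, ncbi, other_refseq, cfg,
                    refseq = refseq)
    } else if (level == 3L) {
      curate_level3(tx, evidence, ncbi, other_refseq, cfg)
    } else {
      act <- if (cfg$keep_level4) "kept_identical" else "deleted"
      outcome(id, 4L, act, if (cfg$keep_level4) tx else NULL, "level4")
    }
    outcomes[[id]] <- oc
  }

  ## rule 3.6: merge co-located level-3 survivors as isoforms
  l3 <- Filter(function(oc) !is.na(oc$level) && oc$level == 3L &&
                 !is.null(oc$result), outcomes)
  if (length(l3) > 1) {
    parts <- split_models(bind_rows(lapply(l3, `[[`, "result")))
    n <- length(parts)
    if (n > 1) {
      sp <- lapply(parts, model_spans)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- sp[[i]]; b <- sp[[j]]
          if (a$chrom != b$chrom) next
          if (!strand_compatible(a$strand, b$strand)) next
          ov <- min(a$span_end, b$span_end) - max(a$span_start, b$span_start)
          shorter <- min(a$span_end - a$span_start, b$span_end - b$span_start)
          if (ov > cfg$isoform_overlap * shorter) {
            parent[find(j)] <- find(i)
          }
        }
      }
      roots <- vapply(seq_len(n), find, integer(1))
      for (r in unique(roots)) {
        grp <- which(roots == r)
        if (length(grp) < 2) next
        merged <- exon_union(parts[grp])
        member_ids <- vapply(parts[grp], function(p) p$transcript_id[1],
                             character(1))
        keep_id <- sort(member_ids)[1]
        merged$transcript_id <- keep_id
        for (mid in member_ids) {
          ## map part id back to its originating model id
          owner <- names(Filter(function(oc)
            mid %in% oc$result$transcript_id, l3))[1]
          oc <- outcomes[[owner]]
          oc$action <- "isoforms_merged"
          oc$rules <- unique(c(oc$rules, "3.6"))
          oc$result <- if (mid == keep_id ||
                             !any(member_ids[member_ids != mid] %in%
                                    oc$result$transcript_id)) {
            others <- filter(oc$result, !.data$transcript_id %in% member_ids)
            if (mid == keep_id) bind_rows(others, merged) else others
          } else oc$result
          if (!is.null(oc$result) && nrow(oc$result) == 0) oc$result <- NULL
          outcomes[[owner]] <- oc
        }
      }
    }
  }

  curated <- bind_rows(lapply(outcomes, `[[`, "result"))
  if (nrow(curated) > 0) {
    curated <- distinct(curated, .data$transcript_id, .data$start, .data$end,
                        .keep_all = TRUE)
    curated <- gene_models(curated)
  } else {
    curated <- empty_models()
  }

  audit <- bind_rows(lapply(outcomes, function(oc) {
    tibble(model_id = oc$model_id, level = oc$level, action = oc$action,
           rules_fired = paste(oc$rules, collapse = ";"),
           evidence_ids = paste(oc$evidence_ids, collapse = ";"),
           n_result = if (is.null(oc$result)) 0L else
             dplyr::n_distinct(oc$result$transcript_id))
  })) |>
    arrange(.data$model_id)

  structure(list(curated = curated, audit = audit, profiles = profiles,
                 config = cfg),
            class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  cat("curation of", nrow(x$audit), "gene models ->",
      dplyr::n_distinct(x$curated$transcript_id), "curated models\n")
  print(dplyr::count(x$audit, .data$level, .data$action))
  invisible(x)
}

#' Audit trail of a curation as a tibble
#' @param x A `curation` object.
#' @param ... Unused.
#' @return The per-model audit tibble.
#' @export
tidy.curation <- function(x, ...) x$audit

#' One-row summary of a curation
#' @param x A `curation` object.
#' @param ... Unused.
#' @return A one-row tibble with model counts per level and action totals.
#' @export
glance.curation <- function(x, ...) {
  tibble(n_input = nrow(x$audit),
         n_curated = dplyr::n_distinct(x$curated$transcript_id),
         n_level1 = sum(x$audit$level == 1, na.rm = TRUE),
         n_level2 = sum(x$audit$level == 2, na.rm = TRUE),
         n_level3 = sum(x$audit$level == 3, na.rm = TRUE),
         n_level4 = sum(x$audit$level == 4, na.rm = TRUE),
         n_unsupported = sum(is.na(x$audit$level)),
         n_deleted = sum(x$audit$action == "deleted"))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
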