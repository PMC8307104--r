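# Report writers and the end-to-end pipeline. All reports are TSV with
# "#"-prefixed metadata headers (inputs, seed, package version) so they are
# machine-parseable and diff-friendly; numeric cells follow the report
# rounding rules (percentages 1 decimal, skews 2 decimals, RSCU and Ka/Ks
# 2 and 5 decimals).

report_header <- function(stage, inputs, seed = NA) {
  c(sprintf("# mitocompare %s report",
            stage),
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("mitocompare"))),
    sprintf("# inputs: %s", paste(inputs, collapse = ", ")),
    if (!is.na(seed)) sprintf("# seed: %s", seed))
}

write_report <- function(df, path, stage, inputs, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(report_header(stage, inputs, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Produces, for a set of annotated genomes: an annotation-accounting report
#' (sizes, spacers, start/stop codons), a per-region and per-codon-position
#' composition report, a pooled RSCU table, a tRNA structure report
#' (arm lengths, pair classes, dot-bracket), a per-gene Ka/Ks table, and
#' supermatrix exports. Any stage failure aborts with a stage-labelled
#' diagnostic and removes partial outputs.
#'
#' @param records Named list of `mito_record` objects.
#' @param out_dir Output directory (created).
#' @param seed Seed recorded in report headers (provenance only).
#' @param kaks_method Aggregation rule for [gene_mean_kaks()].
#' @param relax_ac_loop Passed to [fold_trna()].
#' @return Invisible character vector of files written.
#' @export
run_full_pipeline <- function(records, out_dir, seed = NA,
                              kaks_method = "mean_ratio",
                              relax_ac_loop = FALSE) {
  stopifnot(length(records) >= 1L, !is.null(names(records)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }
  inputs <- names(records)
  run <- function(stage, expr) tryCatch(expr, error = function(e)
    fail(stage, e))

  run("annotate-stats", {
    ann <- do.call(rbind, lapply(names(records), function(nm)
      cbind(species = nm, annotation_summary(records[[nm]]$features))))
    written <- c(written, write_report(
      ann, file.path(out_dir, "annotation.tsv"), "annotation", inputs,
      seed))
  })
  run("composition", {
    comp <- do.call(rbind, lapply(names(records), function(nm) {
      rec <- records[[nm]]
      reg <- cbind(species = nm, block = "region",
                   round_composition(region_composition(rec$genome,
                                                        rec$features)))
      names(reg)[names(reg) == "region"] <- "unit"
      pos <- do.call(rbind, lapply(c("all", "J", "N"), function(sc) {
        d <- round_composition(
          codon_position_composition(rec$genome, rec$features, sc))
        cbind(species = nm, block = paste0("codon_pos_", sc),
              unit = d$position, d[, -1L])
      }))
      rbind(reg, pos)
    }))
    written <- c(written, write_report(
      comp, file.path(out_dir, "composition.tsv"), "composition", inputs,
      seed))
  })
  run("rscu", {
    counts <- count_codons(unlist(lapply(records, pcg_sequences)))
    tab <- rscu(counts)
    tab$rscu <- round(tab$rscu, 2L)
    written <- c(written, write_report(
      tab, file.path(out_dir, "rscu.tsv"), "rscu", inputs, seed))
  })
  run("trna", {
    rows <- do.call(rbind, lapply(names(records), function(nm) {
      rec <- records[[nm]]
      ft <- rec$features
      idx <- which(ft$category == "tRNA")
      do.call(rbind, lapply(idx, function(i) {
        s <- extract_feature_sequence(rec$genome, ft[i, ])
        st <- fold_trna(s, ft$anticodon[i], relax_ac_loop = relax_ac_loop)
        cl <- classify_pairs(st, s)
        data.frame(species = nm, trna = ft$name[i], length = st$length,
                   dhu_present = st$dhu_present,
                   acceptor = st$arm_lengths[["acceptor"]],
                   dhu = st$arm_lengths[["dhu"]],
                   anticodon_stem = st$arm_lengths[["ac"]],
                   tpsic = st$arm_lengths[["tpsic"]],
                   watson_crick = cl$watson_crick,
                   gu_wobble = cl$gu_wobble,
                   mismatches = nrow(cl$mismatches),
                   dot_bracket = st$dot_bracket,
                   stringsAsFactors = FALSE)
      }))
    }))
    written <- c(written, write_report(
      rows, file.path(out_dir, "trna_structure.tsv"), "trna", inputs,
      seed))
  })
  if (length(records) >= 2L) {
    run("kaks", {
      kk <- clade_kaks(records, method = kaks_method)
      kk$mean_ka <- round(kk$mean_ka, 5L)
      kk$mean_ks <- round(kk$mean_ks, 5L)
      kk$mean_ratio <- round(kk$mean_ratio, 5L)
      written <- c(written, write_report(
        kk, file.path(out_dir, "kaks.tsv"), "kaks", inputs, seed))
    })
    run("supermatrix", {
      sm <- build_supermatrix(records)
      written <- c(written,
                    write_supermatrix(sm, file.path(out_dir, "supermatrix")))
      tr <- nj_tree(p_distance_matrix(sm))
      f <- file.path(out_dir, "njtree.nwk")
      ape::write.tree(tr, f)
      written <- c(written, f)
    })
  }
  invisible(written)
}
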