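## Regression checks against published mitogenome records. The records are
## not shipped with the package; point `dir` at a folder of GenBank flat
## files fetched once from NCBI (see ?accessionRegressionChecks).

#' Regression checks on published F/M mitogenome records
#'
#' Recomputes the headline comparative statistics for the *Unio pictorum* /
#' *Sinanodonta woodiana* M-mitogenome study system from locally stored
#' GenBank records: substitution counts between the two sequenced
#' individuals of each species, the whole-genome p-distance between the
#' Chinese and Polish *S. woodiana* M haplotypes, the `cox1` p-distance
#' between *U. pictorum* and *U. delphinus* M genomes, global composition
#' of both sequenced M mitogenomes, and the m-ORF/tRNA duplication report.
#' Records must be complete GenBank flat files named `<accession>.gb`:
#' MH349356, MH349357, MH349358, MH349359, KM434235, KT326918.
#'
#' @param dir directory containing the GenBank records.
#' @return data.frame with columns `check`, `value` (numeric) and `detail`.
#' @export
accessionRegressionChecks <- function(dir) {
  need <- c("MH349356", "MH349357", "MH349358", "MH349359",
            "KM434235", "KT326918")
  paths <- file.path(dir, paste0(need, ".gb"))
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing GenBank records in ", dir, ": ",
         paste(missing, collapse = ", "),
         "; fetch them once from NCBI nuccore (rettype=gbwithparts)")
  g <- setNames(lapply(paths, readGenBank), need)
  up <- countSubstitutions(genomeSeq(g$MH349357), genomeSeq(g$MH349358))
  sw <- countSubstitutions(genomeSeq(g$MH349356), genomeSeq(g$MH349359))
  pch <- genomePDistance(g$KM434235, g$MH349359)
  pcox <- locusPDistance(g$MH349358, g$KT326918, "cox1")
  csw <- globalComposition(g$MH349359)
  cup <- globalComposition(g$MH349358)
  dup <- detectExtraFeatures(g$MH349359, g$MH349358)
  morf <- dup$gained[dup$gained$name == "m-ORF", ]
  extra_trn <- sum(dup$gained$copies_query[grepl("^trn", dup$gained$name)] -
                     dup$gained$copies_reference[grepl("^trn",
                                                       dup$gained$name)])
  data.frame(
    check = c("subs_U_pictorum_pair", "subs_S_woodiana_pair",
              "p_genome_CH_vs_PL", "p_cox1_pictorum_delphinus",
              "at_skew_MH349359", "gc_MH349359",
              "at_skew_MH349358", "gc_MH349358",
              "morf_copies_query", "extra_trn_copies"),
    value = c(up, sw, pch, pcox,
              csw[["at_skew"]], csw[["gc_content"]],
              cup[["at_skew"]], cup[["gc_content"]],
              if (nrow(morf)) morf$copies_query else NA_real_, extra_trn),
    detail = c("MH349357 vs MH349358", "MH349356 vs MH349359",
               "KM434235 vs MH349359, banded whole-genome alignment",
               "MH349358 vs KT326918, cox1",
               "S. woodiana M", "S. woodiana M",
               "U. pictorum M", "U. pictorum M",
               "MH349359 vs MH349358", "MH349359 vs MH349358"),
    stringsAsFactors = FALSE)
}
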