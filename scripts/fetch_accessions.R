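#!/usr/bin/env Rscript
# One-time fetch of the published mitogenome records used by the
# accession-based regression checks (requires network access):
#   Rscript scripts/fetch_accessions.R [destdir]
# Records land in inst/extdata/accessions/<accession>.gb by default, where
# both accessionRegressionChecks() and the acceptance test look for them.

dest <- commandArgs(trailingOnly = TRUE)
dest <- if (length(dest)) dest[1] else file.path("inst", "extdata",
                                                 "accessions")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)
acc <- c("MH349356", "MH349357", "MH349358", "MH349359",
         "KM434235", "KT326917", "KT326918", "HM014133", "HQ283346")
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gbwithparts&retmode=text&id=")
for (a in acc) {
  out <- file.path(dest, paste0(a, ".gb"))
  if (file.exists(out)) next
  message("fetching ", a)
  utils::download.file(paste0(base, a), out, quiet = TRUE)
  Sys.sleep(0.4)  # NCBI rate limit
}
message("done; records in ", dest)
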