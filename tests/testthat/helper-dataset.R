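# Reference paired HK/RR alignment (4069 pairs, DHp 64 + Rec 112 raw
# columns). The file is distributed by the authors of the source dataset
# and is not redistributable inside this package; place it at
# analysis/data/supplementary_dataset4.fasta (repository root) or point
# TCSEVOL_DATASET4 at it.
dataset4_path <- function() {
  cand <- c(Sys.getenv("TCSEVOL_DATASET4", ""),
            testthat::test_path("../../analysis/data/supplementary_dataset4.fasta"),
            "analysis/data/supplementary_dataset4.fasta")
  cand <- cand[nzchar(cand)]
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0L)
    stop("reference paired HK/RR alignment not found; download ",
         "supplementary dataset 4 (4069 aligned HK/RR pairs) to ",
         "analysis/data/supplementary_dataset4.fasta or set ",
         "TCSEVOL_DATASET4")
  hit[[1]]
}

# family-track results on the reference alignment, memoized per session
dataset4_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      aln <- read_paired_alignment(
        dataset4_path(), list(DHp = c(0L, 64L), Rec = c(64L, 176L)))
      cache <<- run_family_track(aln)
    }
    cache
  }
})
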