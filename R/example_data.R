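#' Published handgrip-strength twin-EWAS summary tables
#'
#' Loads the summary tables shipped with the package from a published
#' epigenome-wide association study of handgrip strength in discordant
#' monozygotic twin pairs: `"ewas"` — the 25 genome-wide-significant CpGs
#' (GEE coefficient, p, FDR, nearest gene); `"icefalcon"` — the ICE FALCON
#' change coefficients and published ratios for those CpGs in both causal
#' directions; `"dmr"` — the 21 significant differentially methylated
#' regions with their SLK-corrected p-values.  These printed tables are the
#' worked-example inputs for the desk-scale arithmetic checks (the study's
#' raw sequencing data are not publicly deposited).
#'
#' @param which one of "ewas", "icefalcon", "dmr".
#' @return a data.table.
#' @export
hgs_summary_table <- function(which = c("ewas", "icefalcon", "dmr")) {
  which <- match.arg(which)
  f <- switch(which, ewas = "hgs_ewas_top_cpgs.tsv",
              icefalcon = "hgs_icefalcon_changes.tsv",
              dmr = "hgs_dmr_regions.tsv")
  path <- system.file("extdata", f, package = "mzewas", mustWork = TRUE)
  fread(path, sep = "\t", skip = count_comment_lines(path), header = TRUE,
        na.strings = "NA")
}
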