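#' Controlled vocabulary of brain region codes
#'
#' The sixteen postnatal brain regions with complete lifespan coverage in the
#' BrainSpan developmental transcriptome: anterior cingulate cortex (ACC),
#' amygdala (Amy), cerebellar cortex (Cer), dorsolateral prefrontal cortex
#' (DLPC), hippocampus (Hipp), inferolateral temporal cortex (ITC),
#' mediodorsal thalamus (MTh), orbital frontal cortex (OFC), posterior
#' superior temporal cortex (PSTC), posteroventral parietal cortex (PPC),
#' primary auditory cortex (PAC), primary motor cortex (PMC), primary visual
#' cortex (PVC), primary somatosensory cortex (PSSC), striatum (Str) and
#' ventrolateral prefrontal cortex (VLPC).
#'
#' @return Character vector of the 16 region codes.
#' @export
#' @examples
#' brain_regions()
brain_regions <- function() {
  c("ACC", "Amy", "Cer", "DLPC", "Hipp", "ITC", "MTh", "OFC",
    "PSTC", "PPC", "PAC", "PMC", "PVC", "PSSC", "Str", "VLPC")
}

#' Structure-acronym to region-code mapping
#'
#' Loads the editable lookup table translating atlas structure acronyms
#' (e.g. \code{"DFC"}, \code{"V1C"}) to the controlled 16-code region
#' vocabulary. The default table ships with the package and also accepts the
#' region codes themselves, so round-tripped files map cleanly.
#'
#' @param path Optional path to a two-column TSV (\code{structure_acronym},
#'   \code{region}) overriding the packaged table.
#' @return Named character vector: names are acronyms, values region codes.
#' @export
region_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_map.tsv", package = "ciliascreen")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("structure_acronym", "region") %in% names(tab))) {
    stop("region map must have columns 'structure_acronym' and 'region'")
  }
  bad <- setdiff(tab$region, brain_regions())
  if (length(bad)) {
    stop("region map targets outside the 16-code vocabulary: ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(tab$region, tab$structure_acronym)
}
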