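# data.table is used via :: but its [ syntax must see an aware namespace
.datatable.aware <- TRUE

#' nanoscape: error landscape profiling for nanopore long reads
#'
#' See the package vignette for the underlying models and design choices.
#'
#' @keywords internal
"_PACKAGE"
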