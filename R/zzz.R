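#' @useDynLib hearsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize pchisq p.adjust runif setNames median quantile simulate nlminb
#' @importFrom utils read.table write.table head
NULL

.hearsel_code <- .build_code()
.hearsel_masks <- .build_code_masks(.hearsel_code)

# number of sense codon states under the standard code
.NSTATE <- 61L
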