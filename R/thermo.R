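#' Read a nearest-neighbor parameter table from TSV
#'
#' The file format is two tab-separated columns \code{step} and
#' \code{dg_kcal_mol} (16 dinucleotide steps, 5'->3' on one duplex strand)
#' preceded by optional comment lines; the directives \code{#init_dg=} and
#' \code{#terminal_au=} set the initiation free energy and the terminal
#' A-U penalty (both default to 0 when absent).
#'
#' @param path path to the parameter TSV.
#' @return a validated \linkS4class{NNParameterTable}.
#' @export
readNNParams <- function(path) {
  lines <- readLines(path)
  initDG <- 0
  terminalAU <- 0
  m <- grep("^#init_dg=", lines, value = TRUE)
  if (length(m)) initDG <- as.numeric(sub("^#init_dg=", "", m[1]))
  m <- grep("^#terminal_au=", lines, value = TRUE)
  if (length(m)) terminalAU <- as.numeric(sub("^#terminal_au=", "", m[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("step", "dg_kcal_mol") %in% names(tab)))
    .stopf("parameter table must have columns 'step' and 'dg_kcal_mol'")
  NNParameterTable(stats::setNames(as.numeric(tab$dg_kcal_mol), tab$step),
                   initDG = initDG, terminalAUPenalty = terminalAU)
}

#' The bundled RNA/RNA nearest-neighbor parameter set
#'
#' Published Watson-Crick Delta-G(37) increments (Xia et al. 1998), shipped
#' as a plain-text table under \code{inst/extdata}; see the file header for
#' provenance. Any user table of the same schema can be substituted via
#' \code{\link{readNNParams}}.
#'
#' @return an \linkS4class{NNParameterTable}.
#' @export
defaultNNParams <- function() {
  readNNParams(system.file("extdata", "nn_params_xia1998.tsv",
                           package = "sirnadeep", mustWork = TRUE))
}

.checkGuideCore <- function(guideCore) {
  g <- normalizeRNA(guideCore)
  if (length(g) != 1L || nchar(g) != 19L)
    .stopf("guide core must be a single 19-nt string (the duplexed core of the 21-mer)")
  if (!grepl("^[ACGU]+$", g)) .stopf("guide core contains a non-ACGU symbol")
  g
}

#' Per-step free-energy profile along the duplex
#'
#' Looks up the nearest-neighbor free energy of each of the 18 dinucleotide
#' steps along the 19-nt duplexed core of the guide (antisense) strand.
#' The 21-mer's trailing two nucleotides form the 3' overhang and are
#' excluded from thermodynamics; 18 steps require exactly 19 paired
#' positions.
#'
#' @param guideCore 19-nt RNA string, 5'->3' on the antisense strand.
#' @param params an \linkS4class{NNParameterTable}.
#' @return numeric 18-vector of kcal/mol, element j for the step at
#'   positions (j, j+1).
#' @export
stepProfile <- function(guideCore, params) {
  g <- .checkGuideCore(guideCore)
  ch <- .splitChars(g)[[1]]
  steps <- paste0(ch[1:18], ch[2:19])
  unname(params@stepDG[steps])
}

#' Hybridization stability of the siRNA:target duplex
#'
#' Total free energy of the 19-bp duplex formed between the guide core and
#' its exact complement: initiation term + sum of the 18 step contributions
#' + the terminal A-U penalty for each duplex end closed by an A-U pair.
#' More negative values mean a more stable hybrid.
#'
#' @inheritParams stepProfile
#' @return free energy in kcal/mol.
#' @export
duplexStability <- function(guideCore, params) {
  g <- .checkGuideCore(guideCore)
  ends <- c(substr(g, 1, 1), substr(g, 19, 19))
  penalty <- params@terminalAUPenalty * sum(ends %in% c("A", "U"))
  params@initDG + sum(stepProfile(g, params)) + penalty
}

#' Differential stability of the duplex ends
#'
#' Free energy of the terminal steps at the 5' end of the antisense strand
#' minus that of the terminal steps at its 3' end. This end asymmetry is
#' the classic correlate of guide-strand selection: the strand whose 5' end
#' sits at the less stable duplex end is preferentially loaded into RISC.
#'
#' @inheritParams stepProfile
#' @param endWindow number of terminal steps per end, in [1, 9]; the width
#'   of the "duplex end" is not standardized, so it is configurable and
#'   defaults to the single terminal step.
#' @return kcal/mol; antisymmetric under duplex reversal.
#' @export
endDifferential <- function(guideCore, params, endWindow = 1L) {
  endWindow <- as.integer(endWindow)
  if (endWindow < 1L || endWindow > 9L)
    .stopf("endWindow must be in [1, 9], got %d", endWindow)
  prof <- stepProfile(guideCore, params)
  sum(prof[seq_len(endWindow)]) - sum(prof[seq(19L - endWindow, 18L)])
}

#' The 20-descriptor thermodynamic feature vector
#'
#' Per record: duplex hybridization stability (1), duplex-end differential
#' stability (1), and the 18-step free-energy profile, in that order.
#'
#' @param x a \linkS4class{SiRNASet} or a single 21-nt guide string.
#' @param params an \linkS4class{NNParameterTable}.
#' @param endWindow passed to \code{\link{endDifferential}}.
#' @return numeric matrix with one row per record and 20 named columns
#'   (duplex_dg, end_diff, step_01..step_18).
#' @export
featurizeThermo <- function(x, params, endWindow = 1L) {
  guides <- if (is(x, "SiRNASet")) stats::setNames(x@guide, x@id)
            else stats::setNames(normalizeRNA(x), names(x))
  cores <- substr(guides, 1L, 19L)
  out <- t(vapply(cores, function(g) {
    c(duplexStability(g, params), endDifferential(g, params, endWindow),
      stepProfile(g, params))
  }, numeric(20)))
  colnames(out) <- c("duplex_dg", "end_diff", sprintf("step_%02d", 1:18))
  rownames(out) <- names(guides)
  out
}
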