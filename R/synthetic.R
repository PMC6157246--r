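#' Generate synthetic siRNA records with a known recoverable signal
#'
#' Emulates the shape of compiled siRNA efficacy datasets without any
#' download: sense-strand contexts are drawn i.i.d. from
#' \code{baseComposition}, the guide is the reverse complement of the
#' central 21-nt binding region, and a short motif is planted into the
#' upstream flank of a random subset of "effective" records. The latent
#' signal is
#' \deqn{motifEffect * 1[motif planted] + thermoEffect * endDifferential +
#'   Normal(0, noiseSD)}
#' and the observed efficacy is its logistic transform, so efficacies are
#' guaranteed to lie in (0, 1) and share the model's output range. The
#' ground truth is returned as a sidecar table so tests never re-derive it
#' from the generator's internals.
#'
#' Defaults are the generator's study conditions: 2000 records, motif
#' effect 3.0, thermodynamic end-asymmetry effect 1.0, Gaussian noise 0.1,
#' uniform base composition, an 8-nt motif planted 18 nt upstream of the
#' binding region in half of the records, and 30 nt of available context
#' flank per side (so every flank length up to the scanned maximum of 30
#' is fully observed).
#'
#' @param nRecords number of records.
#' @param motif RNA string planted in the upstream flank of carriers.
#' @param motifEffect latent-scale weight of motif presence.
#' @param thermoEffect latent-scale weight of the duplex end differential
#'   (kcal/mol^-1).
#' @param noiseSD standard deviation of the additive latent noise.
#' @param baseComposition probabilities of A, C, G, U (must sum to 1).
#' @param flankAvail available context flank per side, nt.
#' @param motifOffset distance (nt) from the motif start upstream to the
#'   binding-region start; the motif occupies upstream positions
#'   [motifOffset, motifOffset - length + 1], so it is fully visible to
#'   windows with n >= motifOffset.
#' @param motifFraction fraction of records carrying the motif.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @param params an \linkS4class{NNParameterTable} for the thermodynamic
#'   part of the signal.
#' @return list with \code{records} (a \linkS4class{SiRNASet}) and
#'   \code{truth} (data.frame id, motif_present, end_diff, latent,
#'   efficacy).
#' @export
simulateSiRNA <- function(nRecords, motif = "GGCAUUCG", motifEffect = 3,
                          thermoEffect = 1, noiseSD = 0.1,
                          baseComposition = c(A = 0.25, C = 0.25,
                                              G = 0.25, U = 0.25),
                          flankAvail = 30L, motifOffset = 18L,
                          motifFraction = 0.5, seed = 1L,
                          params = defaultNNParams()) {
  nRecords <- as.integer(nRecords)
  if (nRecords < 1L) .stopf("nRecords must be >= 1")
  if (abs(sum(baseComposition) - 1) > 1e-8)
    .stopf("baseComposition must sum to 1")
  if (noiseSD < 0) .stopf("noiseSD must be >= 0")
  motif <- normalizeRNA(motif)
  if (!grepl("^[ACGU]+$", motif)) .stopf("motif must be an RNA string")
  flankAvail <- as.integer(flankAvail)
  motifOffset <- as.integer(motifOffset)
  if (motifFraction > 0 &&
      (nchar(motif) > motifOffset || motifOffset > flankAvail))
    .stopf("motif (length %d at upstream offset %d) does not fit in the %d-nt flank",
           nchar(motif), motifOffset, flankAvail)
  ctxLen <- 21L + 2L * flankAvail
  withSeed(seed, {
    chars <- sample(RNA_BASES, nRecords * ctxLen, replace = TRUE,
                    prob = baseComposition[RNA_BASES])
    ctx <- matrix(chars, nRecords, ctxLen)
    present <- runif(nRecords) < motifFraction
    mchars <- .splitChars(motif)[[1]]
    mstart <- flankAvail - motifOffset + 1L
    for (i in which(present))
      ctx[i, mstart:(mstart + length(mchars) - 1L)] <- mchars
    context <- apply(ctx, 1, paste, collapse = "")
    binding <- substr(context, flankAvail + 1L, flankAvail + 21L)
    guide <- reverseComplementRNA(binding)
    endDiff <- vapply(substr(guide, 1, 19), endDifferential, numeric(1),
                      params = params)
    latent <- motifEffect * as.numeric(present) + thermoEffect * endDiff +
      rnorm(nRecords, 0, noiseSD)
    eff <- .sigmoid(latent)
    ids <- sprintf("sim%05d", seq_len(nRecords))
    records <- new("SiRNASet", id = ids, guide = guide, context = context,
                   bindingOffset = rep(flankAvail, nRecords),
                   efficacy = eff, source = rep("synthetic", nRecords))
    validObject(records)
    list(records = records,
         truth = data.frame(id = ids, motif_present = present,
                            end_diff = unname(endDiff), latent = latent,
                            efficacy = eff, stringsAsFactors = FALSE))
  })
}
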