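#' Construct / validate a mito-stress-test trace
#'
#' @param time Measurement times (min), strictly increasing.
#' @param ocr Oxygen consumption rates (pmol O2/min); values below zero are
#'   floored at zero.
#' @param injections Named integer vector `c(oligomycin=, fccp=, rotenone=)`
#'   giving the index of the last measurement before each injection; must be
#'   strictly increasing and leave >= 2 measurements per phase.
#' @param ecar Optional extracellular acidification rates (mpH/min).
#' @return A `mito_stress_trace`.
#' @export
mito_stress_trace <- function(time, ocr, injections, ecar = NULL) {
  stopifnot(length(time) == length(ocr), all(diff(time) > 0))
  need <- c("oligomycin", "fccp", "rotenone")
  if (!all(need %in% names(injections)))
    stop("injections must name oligomycin, fccp and rotenone indices")
  inj <- as.integer(injections[need])
  m <- length(ocr)
  if (any(diff(c(0L, inj, m)) < 2))
    stop("every phase needs at least 2 measurements")
  if (any(inj <= 0 | inj >= m)) stop("injection indices out of range")
  structure(list(time = time, ocr = pmax(ocr, 0), ecar = ecar,
                 injections = stats::setNames(inj, need)),
            class = "mito_stress_trace")
}

#' Decompose a mito-stress-test OCR trace into respiration parameters
#'
#' Phase summaries follow the standard report convention: the baseline
#' plateau is the mean of the last three baseline measurements, the
#' post-oligomycin plateau is the phase minimum, the post-FCCP plateau the
#' phase maximum, and the post-rotenone/antimycin-A plateau the phase
#' minimum. From these: `non_mito` = post-rotenone; `basal_mito` = baseline -
#' non_mito; `atp_linked` = baseline - post-oligomycin; `proton_leak` =
#' post-oligomycin - non_mito (so `atp_linked + proton_leak = basal_mito`
#' exactly); `maximal` = post-FCCP - non_mito; `spare_capacity` = maximal -
#' basal_mito. Negative derived rates are reported as-is with a QC flag
#' rather than clipped.
#'
#' @param trace A `mito_stress_trace` (see [mito_stress_trace()] or
#'   [simulate_mito_trace()]).
#' @return List of class `mito_stress_profile` with the six OCR parameters,
#'   `basal_ecar` (mean baseline ECAR, if present) and `qc_warning`.
#' @export
mito_stress_params <- function(trace) {
  stopifnot(inherits(trace, "mito_stress_trace"))
  inj <- trace$injections
  phases <- list(baseline = seq_len(inj["oligomycin"]),
                 oligo = (inj["oligomycin"] + 1):inj["fccp"],
                 fccp = (inj["fccp"] + 1):inj["rotenone"],
                 rot = (inj["rotenone"] + 1):length(trace$ocr))
  if (any(vapply(phases, length, integer(1)) < 2))
    stop("every phase needs at least 2 measurements")
  base_idx <- utils::tail(phases$baseline, 3)
  baseline <- mean(trace$ocr[base_idx])
  post_oligo <- min(trace$ocr[phases$oligo])
  post_fccp <- max(trace$ocr[phases$fccp])
  non_mito <- min(trace$ocr[phases$rot])
  basal_mito <- baseline - non_mito
  atp_linked <- baseline - post_oligo
  proton_leak <- post_oligo - non_mito
  maximal <- post_fccp - non_mito
  spare <- maximal - basal_mito
  vals <- c(basal_mito = basal_mito, atp_linked = atp_linked,
            proton_leak = proton_leak, non_mito = non_mito,
            maximal = maximal, spare_capacity = spare)
  structure(list(basal_mito = basal_mito, atp_linked = atp_linked,
                 proton_leak = proton_leak, non_mito = non_mito,
                 maximal = maximal, spare_capacity = spare,
                 basal_ecar = if (!is.null(trace$ecar))
                   mean(trace$ecar[base_idx]) else NA_real_,
                 qc_warning = any(vals < 0)),
            class = "mito_stress_profile")
}

#' Relative quantification by the 2^-ddCt method
#'
#' For every sample s and target gene g:
#' `dCt(s, g) = Ct(g, s) - Ct(ref, s)`;
#' `ddCt(s, g) = dCt(s, g) - mean over calibrator samples of dCt(., g)`
#' (the calibrator mean is taken on the dCt scale);
#' `RQ = 2^-ddCt`.
#'
#' @param ct `data.frame` with columns `sample_id`, `gene`, `ct` (Ct > 0).
#' @param reference Reference (housekeeping) gene name; every sample must
#'   carry a Ct for it.
#' @param calibrator Character vector of calibrator sample ids (nonempty,
#'   present in the table).
#' @return `data.frame` with one row per (sample, target gene): `sample_id`,
#'   `gene`, `dct`, `ddct`, `rq`.
#' @export
ddct <- function(ct, reference, calibrator) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% colnames(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  calibrator <- unique(calibrator)
  if (length(calibrator) == 0) stop("calibrator sample set is empty")
  if (!all(calibrator %in% ct$sample_id))
    stop("calibrator sample(s) absent from the Ct table: ",
         paste(setdiff(calibrator, ct$sample_id), collapse = ", "))
  ref <- ct[ct$gene == reference, ]
  if (nrow(ref) == 0) stop("reference gene not found: ", reference)
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  targets <- ct[ct$gene != reference, , drop = FALSE]
  no_ref <- setdiff(unique(targets$sample_id), names(ref_ct))
  if (length(no_ref))
    stop("sample(s) without reference-gene Ct: ", paste(no_ref, collapse = ", "))
  targets$dct <- targets$ct - ref_ct[targets$sample_id]
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(tg) {
    cal <- tg$dct[tg$sample_id %in% calibrator]
    if (length(cal) == 0)
      stop("no calibrator measurement for gene ", tg$gene[1])
    tg$ddct <- tg$dct - mean(cal)
    tg$rq <- 2^(-tg$ddct)
    tg[, c("sample_id", "gene", "dct", "ddct", "rq")]
  }))
  rownames(out) <- NULL
  out
}
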