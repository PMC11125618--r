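# Excitation-emission matrix analysis: scatter masking, peak picking,
# shift detection between a reference and a treated EEM.

#' Mask Rayleigh scatter ridges in an EEM
#'
#' Rayleigh scatter appears where emission equals excitation (first order)
#' and where emission equals twice the excitation (second order). Cells
#' within `halfWidthNm` of either ridge are masked; the new mask is OR-ed
#' onto any existing mask, so masking is idempotent and the two orders
#' commute.
#'
#' @param eem an [EEMap-class].
#' @param halfWidthNm ridge half-width in nm (default 15, three grid steps
#'   at a typical 5 nm increment).
#' @return The masked [EEMap-class].
#' @export
maskScatter <- function(eem, halfWidthNm = 15) {
  stopifnot(is(eem, "EEMap"))
  .assertScalarNumber(halfWidthNm, "halfWidthNm")
  if (halfWidthNm < 0)
    stop("'halfWidthNm' must be non-negative", call. = FALSE)
  ex <- eem@excitation
  em <- eem@emission
  d1 <- abs(outer(ex, em, function(x, m) m - x))        # first order
  d2 <- abs(outer(ex, em, function(x, m) m - 2 * x))    # second order
  eem@mask <- eem@mask | d1 <= halfWidthNm | d2 <= halfWidthNm
  validObject(eem)
  eem
}

#' Locate fluorescence peaks in a masked EEM
#'
#' A peak is an unmasked cell whose intensity is at least that of all of
#' its (up to) eight unmasked neighbours. Plateaus of equal-valued adjacent
#' candidates are collapsed to their lexicographically smallest
#' (excitation, emission) cell, so the output is deterministic. Peaks are
#' sorted by intensity (descending, ties lexicographic) and truncated to
#' `maxPeaks`.
#'
#' Residual tails of an imperfectly masked scatter ridge would otherwise
#' always surface as spurious plateau maxima along the mask border, so
#' candidates below `minRelIntensity` of the matrix maximum (masked cells
#' included) are discarded; the floor is relative, keeping the peak list
#' invariant under uniform intensity scaling.
#'
#' @param eem an [EEMap-class], scatter already masked (see
#'   [maskScatter()]).
#' @param maxPeaks maximum number of peaks to return (default 2: the
#'   conventional protein peaks a and b).
#' @param minRelIntensity minimum peak intensity as a fraction of the
#'   matrix maximum (default 0.05).
#' @return A data.frame with columns `label`, `excitation`, `emission`,
#'   `intensity` (zero rows if the matrix is fully masked).
#' @export
eemPeaks <- function(eem, maxPeaks = 2, minRelIntensity = 0.05) {
  stopifnot(is(eem, "EEMap"))
  ival <- eem@intensity
  msk <- eem@mask
  nr <- nrow(ival); nc <- ncol(ival)
  empty <- data.frame(label = character(), excitation = numeric(),
                      emission = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE)
  if (all(msk)) return(empty)
  work <- ival
  work[msk] <- -Inf
  shift <- function(m, di, dj) {
    out <- matrix(-Inf, nr, nc)
    ri0 <- max(1L, 1L + di); ri1 <- min(nr, nr + di)
    rj0 <- max(1L, 1L + dj); rj1 <- min(nc, nc + dj)
    if (ri0 > ri1 || rj0 > rj1) return(out)
    ri <- ri0:ri1; rj <- rj0:rj1
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  nbmax <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nbmax <- pmax(nbmax, shift(work, di, dj))
  }
  floorI <- if (max(ival) > 0) minRelIntensity * max(ival) else -Inf
  cand <- which(!msk & work >= nbmax & ival >= floorI, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  # collapse plateaus: BFS over 8-adjacent candidates of equal intensity
  ord <- order(cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  seen <- rep(FALSE, nrow(cand))
  key <- paste(cand[, 1L], cand[, 2L])
  lookup <- stats::setNames(seq_len(nrow(cand)), key)
  reps <- list()
  for (s in seq_len(nrow(cand))) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    v <- ival[cand[s, 1L], cand[s, 2L]]
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        nk <- paste(cand[cur, 1L] + di, cand[cur, 2L] + dj)
        idx <- lookup[nk]
        if (!is.na(idx) && !seen[idx] &&
            ival[cand[idx, 1L], cand[idx, 2L]] == v) {
          seen[idx] <- TRUE
          queue <- c(queue, idx)
          comp <- c(comp, idx)
        }
      }
    }
    reps[[length(reps) + 1L]] <- cand[min(comp), , drop = FALSE]
  }
  reps <- do.call(rbind, reps)
  pk <- data.frame(excitation = eem@excitation[reps[, 1L]],
                   emission = eem@emission[reps[, 2L]],
                   intensity = ival[reps], stringsAsFactors = FALSE)
  pk <- pk[order(-pk$intensity, pk$excitation, pk$emission), , drop = FALSE]
  pk <- utils::head(pk, maxPeaks)
  rownames(pk) <- NULL
  cbind(label = paste("peak", letters[seq_len(nrow(pk))]), pk,
        stringsAsFactors = FALSE)
}

#' Compare peaks between a reference and a treated EEM
#'
#' Locates peaks in both EEMs (same axes required), matches each reference
#' peak to the nearest treated peak in the (excitation, emission) plane,
#' and reports the emission shift (negative = blue shift), excitation
#' shift, and the treated/reference intensity ratio. Reference peaks with
#' no treated peak within `matchRadiusNm` are flagged unmatched rather than
#' raising an error.
#'
#' @param reference,treated [EEMap-class] objects with identical axes,
#'   scatter already masked.
#' @param maxPeaks number of peaks to locate in each EEM.
#' @param matchRadiusNm maximum Euclidean matching distance, nm.
#' @return A data.frame with one row per reference peak: `label`,
#'   `ref_excitation`, `ref_emission`, `ref_intensity`,
#'   `delta_excitation`, `delta_emission`, `intensity_ratio`, `matched`.
#' @export
compareEEMs <- function(reference, treated, maxPeaks = 2,
                        matchRadiusNm = 20) {
  stopifnot(is(reference, "EEMap"), is(treated, "EEMap"))
  if (!isTRUE(all.equal(reference@excitation, treated@excitation)) ||
      !isTRUE(all.equal(reference@emission, treated@emission)))
    stop("reference and treated EEMs must share the same axes",
         call. = FALSE)
  rp <- eemPeaks(reference, maxPeaks)
  tp <- eemPeaks(treated, maxPeaks)
  if (!nrow(rp))
    stop("no peaks found in the reference EEM", call. = FALSE)
  out <- rp
  names(out) <- c("label", "ref_excitation", "ref_emission", "ref_intensity")
  out$delta_excitation <- NA_real_
  out$delta_emission <- NA_real_
  out$intensity_ratio <- NA_real_
  out$matched <- FALSE
  for (i in seq_len(nrow(rp))) {
    if (!nrow(tp)) break
    d <- sqrt((tp$excitation - rp$excitation[i]) ^ 2 +
              (tp$emission - rp$emission[i]) ^ 2)
    j <- which.min(d)
    if (d[j] <= matchRadiusNm) {
      out$delta_excitation[i] <- tp$excitation[j] - rp$excitation[i]
      out$delta_emission[i] <- tp$emission[j] - rp$emission[i]
      out$intensity_ratio[i] <- tp$intensity[j] / rp$intensity[i]
      out$matched[i] <- TRUE
    }
  }
  out
}
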