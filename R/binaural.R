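#' Monaural response class
#'
#' Classifies a neuron from the significance of its responses to monaural
#' contralateral noise, monaural ipsilateral noise, and the diotic (0 dB
#' ILD) stimulus: `EO` (contra only), `OE` (ipsi only), `EE` (both ears),
#' `OO/F` (diotic only, i.e. binaural facilitation with no monaural
#' response), or `unresponsive`.
#'
#' @param p_contra,p_ipsi,p_diotic one-tailed paired t-test p-values from
#'   [paired_response_p()].
#' @param alpha significance level (default 0.01).
#' @return one of "EO", "OE", "EE", "OO/F", "unresponsive".
#' @export
monaural_class <- function(p_contra, p_ipsi, p_diotic, alpha = 0.01) {
  c_sig <- p_contra < alpha
  i_sig <- p_ipsi < alpha
  d_sig <- p_diotic < alpha
  if (c_sig && i_sig) "EE"
  else if (c_sig) "EO"
  else if (i_sig) "OE"
  else if (d_sig) "OO/F"
  else "unresponsive"
}

#' Binaural interaction index
#'
#' The diotic response divided by the sum of the two monaural responses.
#' Negative mean responses are floored at zero first (ratio categories
#' presuppose nonnegative magnitudes); the index is undefined when the
#' floored monaural sum is zero.
#'
#' @param r_diotic,r_contra,r_ipsi mean responses to the diotic and
#'   monaural stimuli.
#' @return the BII, or NA when undefined.
#' @export
binaural_interaction_index <- function(r_diotic, r_contra, r_ipsi) {
  rd <- max(r_diotic, 0)
  rc <- max(r_contra, 0)
  ri <- max(r_ipsi, 0)
  if (rc + ri <= 0) return(NA_real_)
  rd / (rc + ri)
}

#' Full binaural category
#'
#' Refines the monaural class with the BII: index above 1.2 is binaural
#' facilitation (/F), below 0.8 binaural inhibition (/I), and the closed
#' band \[0.8, 1.2\] is no interaction (/N). An EE neuron with BII < 0.8
#' whose diotic response still exceeds 80% of the dominant-ear monaural
#' response shows binaural occlusion (EE/O); EE with BII < 0.8 and a diotic
#' response at or below that bound is labelled EE/I and reported
#' separately. OO/F passes through unchanged.
#'
#' @param class monaural class from [monaural_class()].
#' @param bii the BII (may be NA for OO/F).
#' @param r_diotic,r_contra,r_ipsi mean responses (used for the EE/O rule).
#' @return the category string.
#' @export
full_category <- function(class, bii, r_diotic = NA, r_contra = NA,
                          r_ipsi = NA) {
  if (class %in% c("OO/F", "unresponsive")) return(class)
  if (!is.finite(bii)) return(paste0(class, "/undefined"))
  if (class %in% c("EO", "OE")) {
    suffix <- if (bii > 1.2) "/F" else if (bii < 0.8) "/I" else "/N"
    return(paste0(class, suffix))
  }
  # EE
  if (bii > 1.2) return("EE/F")
  if (bii >= 0.8) return("EE/N")
  dominant <- max(max(r_contra, 0), max(r_ipsi, 0))
  if (max(r_diotic, 0) > 0.8 * dominant) "EE/O" else "EE/I"
}

#' Classify the binaural properties of all neurons at one ABL
#'
#' For each neuron: paired one-tailed t-tests (pre- vs post-window peaks)
#' for the monaural contralateral, monaural ipsilateral and diotic stimuli
#' at the given ABL, the monaural class, the BII from mean responses
#' (negatives floored), and the full category. Run separately per ABL.
#'
#' @param tensor a `response_tensor` from [extract_responses()].
#' @param abl_db the ABL to classify at.
#' @param alpha significance level for the response t-tests.
#' @return data.frame, one row per neuron: p-values, mean responses,
#'   `monaural_class`, `bii`, `category`.
#' @export
classify_binaural <- function(tensor, abl_db, alpha = 0.01) {
  tr <- tensor$trials
  sel <- function(cls, ild = NULL) {
    i <- tr$stim_class == cls & tr$abl_db == abl_db
    if (!is.null(ild)) i <- i & !is.na(tr$ild_db) & tr$ild_db == ild
    which(i)
  }
  idx_c <- sel("monaural_contra")
  idx_i <- sel("monaural_ipsi")
  idx_d <- sel("binaural", ild = 0)
  if (!length(idx_c) || !length(idx_i) || !length(idx_d))
    stop("monaural and diotic trials at this ABL are required")
  n <- nrow(tensor$responses)
  out <- lapply(seq_len(n), function(j) {
    pc <- paired_response_p(tensor$pre_peaks[j, idx_c],
                            tensor$post_peaks[j, idx_c])
    pi_ <- paired_response_p(tensor$pre_peaks[j, idx_i],
                             tensor$post_peaks[j, idx_i])
    pd <- paired_response_p(tensor$pre_peaks[j, idx_d],
                            tensor$post_peaks[j, idx_d])
    cls <- monaural_class(pc, pi_, pd, alpha)
    rc <- mean(tensor$responses[j, idx_c])
    ri <- mean(tensor$responses[j, idx_i])
    rd <- mean(tensor$responses[j, idx_d])
    bii <- if (cls %in% c("EO", "OE", "EE"))
      binaural_interaction_index(rd, rc, ri) else NA_real_
    data.frame(neuron = j, abl_db = abl_db, p_contra = pc, p_ipsi = pi_,
               p_diotic = pd, r_contra = rc, r_ipsi = ri, r_diotic = rd,
               monaural_class = cls, bii = bii,
               category = full_category(cls, bii, rd, rc, ri),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
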