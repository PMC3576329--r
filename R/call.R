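# Sequential maximum a posteriori classification of minimum-distance
# segments over the 121-state trio space, and ranking of de novo calls.

.subset_trio <- function(trio, idx) {
  structure(list(markers = trio$markers[idx, , drop = FALSE],
                 lrr = trio$lrr[idx, , drop = FALSE],
                 baf = trio$baf[idx, , drop = FALSE]),
            class = "trio_signals")
}

# split a state code into its three symbols
.state_symbols <- function(code) as.integer(strsplit(code, "")[[1L]])

#' Posterior distribution of the trio state over one segment
#'
#' For each of the 121 plausible trio states, the unnormalized log-posterior
#' is the segment log-likelihood plus the log conditional probability of the
#' offspring state given the parents ([offspring_conditional()]) plus, for
#' each parent, the log initial state probability (first segment on the arm)
#' or the log transition probability from the previous segment's MAP state.
#' Posteriors are normalized by log-sum-exp over the state space.
#'
#' @param seg segment as in [segment_loglik()].
#' @param prev_state previous segment's MAP state code, or `NULL` for the
#'   first segment on an arm.
#' @param trio a `trio_signals` object.
#' @param params an [emission_params()] object.
#' @param geno a [genotype_model()].
#' @param p_mendelian prior probability of Mendelian transmission.
#' @param table optional replacement Mendelian transmission table.
#' @return Named numeric vector of 121 normalized posterior probabilities
#'   (summing to 1), with the normalized log-posteriors in attribute
#'   `"log_posterior"`.
#' @export
posterior_table <- function(seg, prev_state = NULL, trio,
                            params = emission_params(),
                            geno = genotype_model(),
                            p_mendelian = 1 - 1.5e-6, table = NULL) {
  if (is.numeric(seg) && length(seg) == 2L)
    seg <- list(start_index = seg[1L], end_index = seg[2L])
  idx <- seq.int(seg$start_index, seg$end_index)
  states <- enumerate_states()$states
  mat <- .state_loglik_matrix(idx, trio, params, geno)
  lp <- vapply(states, function(code) {
    s <- .state_symbols(code)
    ll <- mat[1L, as.character(symbol_cn(s[1L]))] +
      mat[2L, as.character(symbol_cn(s[2L]))] +
      mat[3L, as.character(symbol_cn(s[3L]))]
    off <- log(offspring_conditional(s[1L], s[2L], s[3L], p_mendelian,
                                     table = table))
    par <- if (is.null(prev_state)) {
      sum(log(initial_state_prob(s[1:2])))
    } else {
      ps <- .state_symbols(as.character(prev_state))
      log(parent_transition_prob(ps[1L], s[1L])) +
        log(parent_transition_prob(ps[2L], s[2L]))
    }
    ll + off + par
  }, numeric(1L))
  lse <- max(lp) + log(sum(exp(lp - max(lp))))
  post <- exp(lp - lse)
  attr(post, "log_posterior") <- lp - lse
  post
}

.map_state <- function(post) {
  m <- max(post)
  cand <- names(post)[post == m]
  if ("333" %in% cand) "333" else min(cand)
}

#' Detect de novo CNVs in a case-parent trio
#'
#' The main fitting function. Per chromosome arm it computes the minimum
#' distance, splits the arm at large coverage gaps, segments each region by
#' circular binary segmentation, prunes weak breakpoints, estimates emission
#' parameters by Baum-Welch, and classifies the segments left to right by
#' sequential maximum a posteriori estimation over the 121 trio states, each
#' segment conditioning on the previous segment's MAP state. Ties in the
#' argmax prefer the diploid state 333 (conservative with respect to false
#' de novo calls), then the lexicographically smallest code.
#'
#' @param trio a `trio_signals` object from [assemble_trio()] or the
#'   simulator.
#' @param params a [seg_params()] object.
#' @param p_mendelian prior probability of Mendelian transmission.
#' @param emission_init initial [emission_params()].
#' @param geno a [genotype_model()].
#' @param centromeres optional centromere table from [read_centromeres()];
#'   without it, whole chromosomes are treated as single arms.
#' @param fit_emission estimate emission parameters per arm by
#'   [fit_emission_params()] (`FALSE` keeps `emission_init`).
#' @param max_iter,tol Baum-Welch iteration controls.
#' @return An object of class `mdcnv` with components `calls` (data frame:
#'   one row per segment with chromosome, arm, 1-based inclusive basepair
#'   bounds, coverage, segment mean minimum distance, MAP state code,
#'   `map_posterior`, `log10_odds_vs_diploid` and `is_de_novo`), `mindist`,
#'   `segments`, per-arm fitted `emission` parameters, and the call
#'   configuration.
#' @export
call_trio <- function(trio, params = seg_params(),
                      p_mendelian = 1 - 1.5e-6,
                      emission_init = emission_params(),
                      geno = genotype_model(), centromeres = NULL,
                      fit_emission = TRUE, max_iter = 10L, tol = 1e-3) {
  stopifnot(inherits(trio, "trio_signals"))
  md <- minimum_distance(trio)
  arm <- .assign_arms(trio$markers, centromeres)
  arm_key <- paste0(trio$markers$chrom, arm)
  mend_tab <- mendelian_table()
  calls <- list()
  emission_fits <- list()

  for (key in unique(arm_key)) {
    rows <- which(arm_key == key)
    sub <- .subset_trio(trio, rows)
    d <- md$d[rows]
    this_chrom <- sub$markers$chrom[1L]
    this_arm <- arm[rows[1L]]

    regions <- split_by_gaps(sub$markers$position, params)
    segs <- do.call(rbind, lapply(seq_len(nrow(regions)), function(r) {
      ridx <- seq.int(regions$start[r], regions$end[r])
      s <- cbs_segment(d[ridx], params)
      s <- prune_segments(s, d[ridx], params)
      s$start_index <- s$start_index + regions$start[r] - 1L
      s$end_index <- s$end_index + regions$start[r] - 1L
      s
    }))

    em <- if (fit_emission)
      fit_emission_params(sub, emission_init, max_iter = max_iter, tol = tol,
                          geno = geno)
    else emission_init
    emission_fits[[key]] <- em

    prev <- NULL
    for (j in seq_len(nrow(segs))) {
      post <- posterior_table(segs[j, ], prev, sub, em, geno, p_mendelian,
                              table = mend_tab)
      state <- .map_state(post)
      lp <- attr(post, "log_posterior")
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = this_chrom, arm = this_arm,
        start_bp = sub$markers$position[segs$start_index[j]],
        end_bp = sub$markers$position[segs$end_index[j]],
        start_index = rows[segs$start_index[j]],
        end_index = rows[segs$end_index[j]],
        n_markers = segs$coverage[j], mean_d = segs$mean_d[j],
        state = state, map_posterior = unname(post[state]),
        log10_odds_vs_diploid = unname(lp[state] - lp["333"]) / log(10),
        is_de_novo = is_de_novo(state), stringsAsFactors = FALSE)
      prev <- state
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  structure(list(calls = calls, mindist = md,
                 emission = emission_fits,
                 n_markers = nrow(trio$markers),
                 params = params, p_mendelian = p_mendelian,
                 fit_emission = fit_emission),
            class = "mdcnv")
}

#' Rank de novo calls by posterior odds against the diploid state
#'
#' De novo calls sorted by descending odds of the MAP state versus the all-
#' diploid state 333; ties broken by descending coverage, then genomic order.
#'
#' @param calls an `mdcnv` fit or its `calls` data frame.
#' @return Data frame of the de novo calls in rank order.
#' @export
rank_calls <- function(calls) {
  if (inherits(calls, "mdcnv")) calls <- calls$calls
  dn <- calls[calls$is_de_novo, , drop = FALSE]
  dn <- dn[order(-dn$log10_odds_vs_diploid, -dn$n_markers, dn$chrom,
                 dn$start_bp), , drop = FALSE]
  rownames(dn) <- NULL
  dn
}
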