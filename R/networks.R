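#' Merge the 14-network labeling into the 12 analysis networks
#'
#' Combines the Somatomotor-Dorsal (SMd) and Somatomotor-Lateral (SMl)
#' networks into a single SM network and drops the Unassigned ROIs,
#' leaving the 12 networks used in all analyses.
#'
#' @param parcellation Data frame with `roi_id` and `network` (14-network
#'   labels), or a character vector of labels.
#' @return Same shape as the input, restricted to analysis ROIs, with
#'   `network` relabeled; the dropped ROI ids are kept in attribute
#'   `dropped_rois` (for vectors, names index the original positions).
#' @export
merge_networks <- function(parcellation) {
  as_vec <- is.character(parcellation)
  labels <- if (as_vec) parcellation else parcellation$network
  bad <- setdiff(unique(labels), NETWORKS_14)
  if (length(bad))
    stop("unknown network label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  merged <- ifelse(labels %in% c("SMd", "SMl"), "SM", labels)
  keep <- merged != "Unassigned"
  if (as_vec) {
    out <- merged[keep]
    attr(out, "dropped_rois") <- which(!keep)
    return(out)
  }
  out <- parcellation[keep, , drop = FALSE]
  out$network <- merged[keep]
  rownames(out) <- NULL
  attr(out, "dropped_rois") <- parcellation$roi_id[!keep]
  out
}

#' Within/between-network connectivity and segregation
#'
#' Computes, for each network *k* over a thresholded Fisher-z matrix:
#' within-network connectivity `Zw_k` (mean over all unordered ROI pairs
#' inside *k*, diagonal excluded), between-network connectivity `Zb_k`
#' (mean over all pairs of one ROI in *k* with every ROI outside *k*, over
#' the full analysis ROI set), pairwise network-to-network means
#' `Zb_{k,l}`, and segregation `S_k = (Zw_k - Zb_k) / Zw_k`. Global
#' summaries weight every network equally regardless of its size:
#' `W = mean(Zw_k)`, `B = mean(Zb_k)` and `S_global = (W - B) / W`; the
#' alternative global summary `mean(S_k)` is reported alongside.
#'
#' @param z Thresholded Fisher-z connectivity matrix over the analysis
#'   ROIs (e.g. after [merge_networks()] and [threshold_negative()]).
#' @param labels Character vector of network labels, one per ROI
#'   (row/column) of `z`.
#' @return List with `networks` (data frame: `network`, `within`,
#'   `between`, `segregation`), `pairwise` (data frame: `net_a`, `net_b`,
#'   `z`, both orders collapsed to one row per unordered pair), and
#'   `global` (named vector `W`, `B`, `segregation`, `mean_segregation`).
#' @examples
#' z <- matrix(0.1, 4, 4); z[1, 2] <- z[2, 1] <- 0.6
#' z[3, 4] <- z[4, 3] <- 0.4; diag(z) <- NA
#' network_measures(z, c("A", "A", "B", "B"))
#' @export
network_measures <- function(z, labels) {
  z <- as.matrix(z)
  stopifnot(nrow(z) == ncol(z), length(labels) == nrow(z))
  nets <- unique(labels)
  counts <- table(labels)
  if (any(counts < 2))
    stop("every network needs at least 2 ROIs: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  zw <- zb <- setNames(numeric(length(nets)), nets)
  for (k in nets) {
    idx <- labels == k
    wk <- z[idx, idx]
    zw[k] <- mean(wk[upper.tri(wk)], na.rm = TRUE)
    zb[k] <- mean(z[idx, !idx], na.rm = TRUE)
  }
  seg <- ifelse(zw > 0, (zw - zb) / zw, NA_real_)
  if (any(zw <= 0, na.rm = TRUE))
    warning("within-network connectivity <= 0 for: ",
            paste(nets[which(zw <= 0)], collapse = ", "),
            "; segregation undefined", call. = FALSE)
  pw <- expand.grid(net_a = nets, net_b = nets, stringsAsFactors = FALSE)
  pw <- pw[match(pw$net_a, nets) < match(pw$net_b, nets), ]
  pw$z <- mapply(function(a, b) mean(z[labels == a, labels == b],
                                     na.rm = TRUE),
                 pw$net_a, pw$net_b)
  rownames(pw) <- NULL
  W <- mean(zw); B <- mean(zb)
  list(networks = data.frame(network = nets, within = unname(zw),
                             between = unname(zb),
                             segregation = unname(seg),
                             stringsAsFactors = FALSE),
       pairwise = pw,
       global = c(W = W, B = B, segregation = (W - B) / W,
                  mean_segregation = mean(seg)))
}

#' Assemble cohort-level network measures
#'
#' Stacks per-subject [network_measures()] into long tables and joins the
#' per-subject motion summary and behavioral scores.
#'
#' @param matrices Named list (by subject id) of thresholded Fisher-z
#'   matrices over the analysis ROIs.
#' @param labels Network labels shared by all subjects.
#' @param qc Optional data frame with `subject_id` and `rms_fd`.
#' @param behavior Optional data frame with `subject_id` and
#'   `valence_bias`.
#' @return List with `measures` (one row per subject x network plus one
#'   `global` row per subject) and `pairwise` (one row per subject and
#'   unordered network pair).
#' @export
cohort_measures <- function(matrices, labels, qc = NULL, behavior = NULL) {
  ids <- names(matrices)
  stopifnot(!is.null(ids))
  for (tbl in list(qc, behavior)) {
    if (!is.null(tbl)) {
      orphan <- setdiff(ids, tbl$subject_id)
      if (length(orphan))
        stop("subjects missing from join table: ",
             paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  rows <- pw_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    nm <- network_measures(matrices[[i]], labels)
    net <- nm$networks
    net <- rbind(net, data.frame(network = "global",
                                 within = nm$global["W"],
                                 between = nm$global["B"],
                                 segregation = nm$global["segregation"]))
    net$subject_id <- ids[i]
    rows[[i]] <- net
    p <- nm$pairwise
    p$subject_id <- ids[i]
    pw_rows[[i]] <- p
  }
  measures <- do.call(rbind, rows)
  pairwise <- do.call(rbind, pw_rows)
  rownames(measures) <- rownames(pairwise) <- NULL
  measures <- measures[, c("subject_id", "network", "within", "between",
                           "segregation")]
  pairwise <- pairwise[, c("subject_id", "net_a", "net_b", "z")]
  if (!is.null(qc))
    measures <- merge(measures, qc[, c("subject_id", "rms_fd")],
                      by = "subject_id", sort = FALSE)
  if (!is.null(behavior))
    measures <- merge(measures,
                      behavior[, c("subject_id", "valence_bias")],
                      by = "subject_id", sort = FALSE)
  list(measures = measures, pairwise = pairwise)
}
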