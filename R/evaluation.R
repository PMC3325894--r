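# Evaluation protocol: essentiality annotations, deterministic ranking,
# top-k essential counts, jackknife cumulative curves with AUC and random
# baselines, and overlap / difference reports between measures.

.status_levels <- c("essential", "nonessential", "unknown")

#' Merge essentiality source lists into one annotation
#'
#' A protein is essential if it appears in at least one essential source
#' list; nonessential if it appears in a nonessential list and in no
#' essential list; otherwise unknown. Every protein of `universe` is covered.
#'
#' @param essential A character vector, or list of character vectors, of
#'   proteins marked essential by some source database.
#' @param nonessential As `essential`, for proteins marked nonessential.
#' @param universe Character vector of all proteins to annotate (typically
#'   the network node set).
#' @return Named character vector over `universe` with values
#'   `"essential"`, `"nonessential"` or `"unknown"`.
#' @export
merge_annotations <- function(essential, nonessential = character(0L),
                              universe) {
  ess <- unique(unlist(essential, use.names = FALSE))
  non <- unique(unlist(nonessential, use.names = FALSE))
  status <- stats::setNames(rep("unknown", length(universe)), universe)
  status[universe %in% non] <- "nonessential"
  status[universe %in% ess] <- "essential"
  status
}

#' Read an essentiality annotation file
#'
#' Two tab-separated columns: protein identifier and status (`essential`,
#' `nonessential` or `unknown`). Proteins of `universe` absent from the file
#' are annotated `unknown`.
#'
#' @param path Path to the annotation TSV.
#' @param universe Optional character vector of proteins the annotation must
#'   cover.
#' @return Named status vector as in [merge_annotations()].
#' @export
read_annotation <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, col.names = c("protein", "status"),
                          colClasses = "character", stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$status), .status_levels)
  if (length(bad) > 0L) {
    stop("invalid essentiality status: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$protein)) {
    stop("duplicate protein in annotation file: ",
         df$protein[duplicated(df$protein)][1L])
  }
  status <- stats::setNames(df$status, df$protein)
  if (!is.null(universe)) {
    full <- stats::setNames(rep("unknown", length(universe)), universe)
    hit <- intersect(universe, names(status))
    full[hit] <- status[hit]
    status <- full
  }
  status
}

#' Write an essentiality annotation file
#' @param ann Named status vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  writeLines(paste(names(ann), ann, sep = "\t"), path)
  invisible(path)
}

#' Rank proteins by a centrality score
#'
#' Descending score; ties broken by ascending protein identifier, so the
#' ranking is a deterministic permutation of the node set.
#'
#' @param scores A [score_vector()] (named numeric vector).
#' @return A `data.frame` with columns `protein`, `score`, ordered by rank;
#'   the measure label is kept in the `"measure"` attribute.
#' @export
rank_proteins <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ord <- order(-scores, names(scores))
  out <- data.frame(protein = names(scores)[ord],
                    score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- attr(scores, "measure")
  out
}

.ranked_proteins <- function(ranked) {
  if (is.data.frame(ranked)) ranked$protein else as.character(ranked)
}

#' Count essential proteins among the top k of a ranking
#'
#' Unknown-status proteins count as not essential, so the count is a lower
#' bound on the true precision.
#'
#' @param ranked Ranking from [rank_proteins()] (or a character vector of
#'   proteins in rank order).
#' @param ann Named status vector.
#' @param k Number of top candidates, `1 <= k <= n`.
#' @return Integer count of essentials among the first `k`.
#' @export
top_k_essential <- function(ranked, ann, k) {
  prot <- .ranked_proteins(ranked)
  if (length(k) != 1L || k < 1L || k > length(prot)) {
    stop("k must satisfy 1 <= k <= ", length(prot))
  }
  sum(ann[prot[seq_len(k)]] == "essential", na.rm = TRUE)
}

#' Jackknife cumulative-essential curve and its AUC
#'
#' Walks the ranking from the highest-scoring protein downward and records
#' the cumulative count of true essentials at every rank. The AUC is the
#' mean cumulative count divided by the total number of essentials
#' (rectangle rule, normalized so a perfect ranking of E essentials among n
#' proteins scores 1 - (E - 1) / (2n) and a random ranking about 1/2).
#'
#' @inheritParams top_k_essential
#' @return An object of class `"jackknife_curve"`: a list with `measure`,
#'   `cumulative` (integer vector, one entry per rank) and `auc`.
#' @export
jackknife <- function(ranked, ann) {
  prot <- .ranked_proteins(ranked)
  ess <- !is.na(ann[prot]) & ann[prot] == "essential"
  cum <- cumsum(ess)
  n_ess <- sum(ess)
  auc <- if (n_ess > 0L) mean(cum) / n_ess else NA_real_
  structure(list(measure = attr(ranked, "measure"),
                 cumulative = as.integer(cum),
                 auc = auc),
            class = "jackknife_curve")
}

#' @export
print.jackknife_curve <- function(x, ...) {
  cat(sprintf("Jackknife curve%s: %d proteins, %d essential, AUC = %.4f\n",
              if (is.null(x$measure)) "" else paste0(" (", x$measure, ")"),
              length(x$cumulative),
              if (length(x$cumulative)) x$cumulative[length(x$cumulative)] else 0L,
              x$auc))
  invisible(x)
}

#' Jackknife AUC of a ranking
#' @inheritParams top_k_essential
#' @return The AUC, a single value in `[0, 1]`.
#' @export
jackknife_auc <- function(ranked, ann) jackknife(ranked, ann)$auc

#' Random-assortment baseline curves
#'
#' Uniformly random orderings of the node set turned into jackknife curves;
#' the paper-style baseline a real measure must beat. Reproducible from
#' `seed`.
#'
#' @param net An `igraph` network (its node set is permuted).
#' @param ann Named status vector.
#' @param count Number of assortments (default 10).
#' @param seed Optional integer seed (sets the session RNG).
#' @return List of `count` [jackknife()] curves, measure `"random"`.
#' @export
random_assortments <- function(net, ann, count = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- igraph::V(net)$name
  lapply(seq_len(count), function(i) {
    perm <- sample(nms)
    ranked <- data.frame(protein = perm,
                         score = rev(seq_along(perm)),
                         stringsAsFactors = FALSE)
    attr(ranked, "measure") <- "random"
    jackknife(ranked, ann)
  })
}

#' Overlap report between a reference measure and a comparison measure
#'
#' Mirrors the paper-style top-k overlap table: how many of the comparison
#' measure's top-k candidates the reference measure (typically PeC) also
#' finds, how many it does not, how many of the latter are annotated
#' nonessential, and what percentage of those nonessentials have a low
#' reference score.
#'
#' @param ref_ranked Reference ranking from [rank_proteins()]; its `score`
#'   column supplies the low-score screen.
#' @param other_ranked Comparison ranking.
#' @param ann Named status vector.
#' @param k Top-list size.
#' @param low_threshold Reference-score threshold for the "low" screen
#'   (default 0.55).
#' @return A one-row `data.frame` with columns `measure`, `k`,
#'   `common_count`, `diff_count`, `nonessential_in_diff`,
#'   `pct_nonessential_low` (percentage 0-100; 0 when there are no
#'   nonessentials in the difference set).
#' @export
overlap_analysis <- function(ref_ranked, other_ranked, ann, k,
                             low_threshold = 0.55) {
  ref_top <- .ranked_proteins(ref_ranked)[seq_len(k)]
  oth_top <- .ranked_proteins(other_ranked)[seq_len(k)]
  common <- intersect(oth_top, ref_top)
  diff <- setdiff(oth_top, ref_top)
  non <- diff[!is.na(ann[diff]) & ann[diff] == "nonessential"]
  ref_scores <- stats::setNames(ref_ranked$score, ref_ranked$protein)
  pct_low <- if (length(non) > 0L) {
    100 * mean(ref_scores[non] < low_threshold)
  } else 0
  data.frame(
    measure = if (is.null(attr(other_ranked, "measure"))) NA_character_
              else attr(other_ranked, "measure"),
    k = as.integer(k),
    common_count = length(common),
    diff_count = length(diff),
    nonessential_in_diff = length(non),
    pct_nonessential_low = pct_low,
    stringsAsFactors = FALSE
  )
}

#' Essential percentage within the difference sets of two rankings
#'
#' Among the proteins ranked in `a`'s top k but not in `b`'s, the percentage
#' annotated essential — and symmetrically. When the two top-k sets are
#' identical both percentages are reported as 0 with
#' `empty_difference = TRUE`.
#'
#' @param a_ranked,b_ranked Rankings from [rank_proteins()].
#' @param ann Named status vector.
#' @param k Top-list size.
#' @return A list with `pct_a`, `pct_b` (percentages 0-100) and
#'   `empty_difference`.
#' @export
difference_essential_pct <- function(a_ranked, b_ranked, ann, k) {
  a_top <- .ranked_proteins(a_ranked)[seq_len(k)]
  b_top <- .ranked_proteins(b_ranked)[seq_len(k)]
  diff_a <- setdiff(a_top, b_top)
  diff_b <- setdiff(b_top, a_top)
  pct <- function(set) {
    if (length(set) == 0L) 0
    else 100 * mean(!is.na(ann[set]) & ann[set] == "essential")
  }
  list(pct_a = pct(diff_a), pct_b = pct(diff_b),
       empty_difference = length(diff_a) == 0L && length(diff_b) == 0L)
}
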