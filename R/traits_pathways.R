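#' Relative genomic plasticity per taxon
#'
#' For taxon `i`, the mean over all other taxa `j` of the difference between
#' the marker-gene (16S) dissimilarity and the proteome dissimilarity:
#' `plasticity(i) = mean_j (d_gene(i, j) - d_proteome(i, j))`. A large
#' magnitude means the taxon's functional (proteome) divergence is decoupled
#' from its phylogenetic (marker-gene) divergence. The literal gene-minus-
#' proteome convention is the default; the opposite sign and an
#' absolute-value variant are available because either direction of
#' decoupling can be of interest.
#'
#' @param d_gene,d_proteome Symmetric taxon-pairwise dissimilarity matrices
#'   over the same taxa (matrix or `dist`).
#' @param sign `"gene_minus_proteome"` (default) or `"proteome_minus_gene"`.
#' @param absolute Return absolute per-pair differences before averaging.
#' @return Tibble with `taxon_id` and `plasticity`.
#' @export
genomic_plasticity <- function(d_gene, d_proteome,
                               sign = c("gene_minus_proteome",
                                        "proteome_minus_gene"),
                               absolute = FALSE) {
  sign <- match.arg(sign)
  g <- as.matrix(d_gene)
  p <- as.matrix(d_proteome)
  if (!identical(dim(g), dim(p))) abort("dissimilarity matrices differ in size")
  if (!is.null(rownames(g)) && !is.null(rownames(p)) &&
      !identical(rownames(g), rownames(p))) {
    abort("dissimilarity matrices cover different taxa")
  }
  n <- nrow(g)
  if (n < 2) abort("need at least 2 taxa")
  diffm <- g - p
  if (sign == "proteome_minus_gene") diffm <- -diffm
  if (absolute) diffm <- abs(diffm)
  diag(diffm) <- 0
  tibble::tibble(
    taxon_id = rownames(g) %||% as.character(seq_len(n)),
    plasticity = unname(rowSums(diffm)) / (n - 1))
}

#' Community-weighted mean genome traits per sample
#'
#' `CWM = sum_i w_i * trait_i` with weights `w_i` the relative abundances
#' renormalized over taxa with a non-missing value of that trait. Growth
#' rate is derived as `log(2) / doubling_time_h` when a doubling-time column
#' is present. The fraction of each sample's reads carried by
#' trait-complete taxa is reported per trait as a coverage column.
#'
#' @param counts A count table.
#' @param traits Trait table with `taxon_id` and numeric trait columns
#'   (`genome_size_bp`, `n_coding_sequences`, `doubling_time_h`, optionally
#'   `plasticity`).
#' @return Tibble keyed by `sample_id` with one `cwm_*` and one
#'   `coverage_*` column per trait (growth rate replaces doubling time).
#' @export
community_weighted_traits <- function(counts, traits) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  mat <- count_matrix(counts)
  traits <- tibble::as_tibble(traits)
  taxa <- colnames(mat)
  idx <- match(taxa, traits$taxon_id)
  trait_cols <- setdiff(names(traits), "taxon_id")
  trait_cols <- trait_cols[vapply(traits[trait_cols], is.numeric, logical(1))]
  tr <- traits[idx, trait_cols, drop = FALSE]
  if ("doubling_time_h" %in% trait_cols) {
    tr$growth_rate <- log(2) / tr$doubling_time_h
    tr$doubling_time_h <- NULL
  }
  out <- tibble::tibble(sample_id = rownames(mat))
  for (tc in names(tr)) {
    v <- tr[[tc]]
    ok <- !is.na(v)
    if (!any(ok)) {
      warn(sprintf("no taxon has trait '%s'; returning NA", tc))
      out[[paste0("cwm_", tc)]] <- NA_real_
      out[[paste0("coverage_", tc)]] <- 0
      next
    }
    w <- mat[, ok, drop = FALSE]
    tot_ok <- unname(rowSums(w))
    cwm <- as.numeric(w %*% v[ok]) / tot_ok
    none <- tot_ok == 0
    if (any(none)) {
      warn(sprintf("sample(s) with no counts on trait-complete taxa for '%s': %s",
                   tc, paste(rownames(mat)[none], collapse = ", ")))
      cwm[none] <- NA_real_
    }
    out[[paste0("cwm_", tc)]] <- cwm
    out[[paste0("coverage_", tc)]] <- tot_ok / unname(rowSums(mat))
  }
  out
}

#' Aggregate counts into pathway abundances
#'
#' `abundance(pathway, sample) = sum of counts of the pathway's member
#' taxa`. Pathways with no member among the counted taxa are excluded with a
#' warning.
#'
#' @param counts A count table.
#' @param incidence Pathway-by-taxon binary incidence: tibble with
#'   `pathway_id` and one 0/1 column per taxon, or a binary matrix with
#'   pathway rownames.
#' @return Tibble with `pathway_id`, `n_member_taxa`, and one column per
#'   sample.
#' @export
pathway_abundance <- function(counts, incidence) {
  counts <- validate_count_table(counts, require_positive = FALSE)
  mat <- count_matrix(counts)
  if (is.data.frame(incidence)) {
    inc <- as.matrix(incidence[setdiff(names(incidence), "pathway_id")])
    rownames(inc) <- incidence$pathway_id
  } else {
    inc <- as.matrix(incidence)
  }
  if (!all(inc %in% c(0, 1))) abort("incidence must be binary")
  common <- intersect(colnames(mat), colnames(inc))
  if (length(common) == 0) abort("no shared taxa between counts and incidence")
  inc <- inc[, common, drop = FALSE]
  members <- rowSums(inc)
  if (any(members == 0)) {
    warn(paste0("excluding pathway(s) with no member taxa: ",
                paste(rownames(inc)[members == 0], collapse = ", ")))
    inc <- inc[members > 0, , drop = FALSE]
    members <- members[members > 0]
  }
  ab <- inc %*% t(mat[, common, drop = FALSE])  # pathway x sample
  dplyr::bind_cols(
    tibble::tibble(pathway_id = rownames(inc),
                   n_member_taxa = as.integer(members)),
    tibble::as_tibble(ab))
}

# DESeq-style median-of-ratios size factors over pathway rows
size_factors <- function(ab) {
  logg <- rowMeans(log(ab + (ab == 0)))  # log geometric mean, 0s neutralized
  use <- rowSums(ab > 0) == ncol(ab)
  if (!any(use)) return(rep(1, ncol(ab)))
  sf <- apply(ab[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logg[use]))
  })
  sf / exp(mean(log(sf)))
}

#' Differential pathway abundance along the loading gradient
#'
#' Per pathway: abundances are depth-normalized by median-of-ratios size
#' factors, log2-transformed with a pseudocount, and regressed on the
#' centered-and-scaled loading. The slope is the log2 fold change per one
#' standard deviation of loading (a log2FC of +2 means the pathway is 4x
#' more abundant one SD above the mean loading than at the mean). P-values
#' come from permutation of the loading labels (two-sided on |slope|),
#' shared across pathways. A pathway passes the filters iff `p <
#' p_threshold`, `|log2FC| > min_abs_log2fc`, and it occurs in at least
#' `min_taxa` member taxa.
#'
#' @param pathways Pathway abundance table from [pathway_abundance()]
#'   (`pathway_id`, `n_member_taxa`, sample columns).
#' @param loading Loading in grams per sample column, in column order.
#' @param n_perm Permutations (default 999).
#' @param seed Optional seed.
#' @param p_threshold,min_abs_log2fc,min_taxa Filter thresholds (defaults
#'   0.01, 2, 5).
#' @param pseudocount Added to normalized abundances before log2 (default 1).
#' @return Tibble of class `differential_pathways`: `pathway_id`, `log2fc`,
#'   `p`, `n_member_taxa`, `passes_filters`, `skipped` (constant rows).
#' @export
differential_pathways <- function(pathways, loading, n_perm = 999,
                                  seed = NULL, p_threshold = 0.01,
                                  min_abs_log2fc = 2, min_taxa = 5,
                                  pseudocount = 1) {
  meta_cols <- intersect(c("pathway_id", "n_member_taxa"), names(pathways))
  ab <- as.matrix(pathways[setdiff(names(pathways), meta_cols)])
  rownames(ab) <- pathways$pathway_id
  n <- ncol(ab)
  if (n < 6) abort("need at least 6 samples")
  if (length(loading) != n) abort("loading length must match sample columns")
  if (length(unique(loading)) < 2) abort("loading must vary")

  sf <- size_factors(ab)
  norm <- sweep(ab, 2, sf, "/")
  y <- log2(norm + pseudocount)
  x <- as.numeric(scale(loading))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- y - rowMeans(y)
  slopes <- as.numeric(yc %*% xc) / sxx
  # flag on the raw abundances: size-factor scaling can make a constant
  # row formally vary without carrying information
  constant <- unname(apply(ab, 1, function(r) length(unique(r)) == 1))

  with_seed_or_not(seed, {
    perm_idx <- make_permutations(n, n_perm)
    xp <- matrix(xc[perm_idx], nrow = n)
    xp <- sweep(xp, 2, colMeans(xp))
    slopes_perm <- (yc %*% xp) / sxx           # pathway x perm
    exceed <- rowSums(abs(slopes_perm) >= abs(slopes) - 1e-12)
    p <- (exceed + 1) / (n_perm + 1)
    p[constant] <- NA_real_
    n_taxa <- if ("n_member_taxa" %in% names(pathways)) {
      pathways$n_member_taxa
    } else {
      rep(NA_integer_, nrow(ab))
    }
    out <- tibble::tibble(
      pathway_id = rownames(ab),
      log2fc = ifelse(constant, NA_real_, slopes),
      p = p,
      n_member_taxa = n_taxa,
      skipped = constant)
    out$passes_filters <- !out$skipped &
      !is.na(out$p) & out$p < p_threshold &
      abs(out$log2fc) > min_abs_log2fc &
      !is.na(out$n_member_taxa) & out$n_member_taxa >= min_taxa
    class(out) <- c("differential_pathways", class(out))
    out
  })
}

#' Categorize significant pathway sets from two sampling days
#'
#' Splits the union of the early-day and late-day significant pathway sets
#' into pathways significant only early, only late, or at both times;
#' `|only_early| + |only_late| + |both| = |union|` by construction.
#'
#' @param early,late Character vectors of significant pathway ids at the
#'   early and late day.
#' @return Tibble with `pathway_id` and `category` (`only_early`,
#'   `only_late`, `both`); summary counts in the `"counts"` attribute.
#' @export
categorize_pathways <- function(early, late) {
  all_ids <- union(early, late)
  category <- dplyr::case_when(
    all_ids %in% early & all_ids %in% late ~ "both",
    all_ids %in% early ~ "only_early",
    TRUE ~ "only_late")
  out <- tibble::tibble(pathway_id = all_ids, category = category)
  attr(out, "counts") <- c(
    only_early = sum(category == "only_early"),
    only_late = sum(category == "only_late"),
    both = sum(category == "both"),
    total = length(all_ids))
  out
}
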