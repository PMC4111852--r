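# Functional-impact scoring rule, construction of the paired
# non-synonymous/synonymous mutation matrix, and the per-gene
# Mutation Factor (MF).

.nsy_classes <- c("missense", "nonsense", "indel", "splice_site")

#' Impact-score bounds for the cohort scoring rule
#'
#' The scoring rule assigns the highest attainable functional-impact score to
#' indels, nonsense and splice-site mutations (assumed at least as disruptive
#' as the most disruptive scored missense change), the lowest attainable score
#' to synonymous mutations, and the cohort mean of all scored missense impacts
#' to missense mutations lacking a score.
#'
#' @param ma_max Highest attainable impact score.
#' @param ma_min Lowest attainable impact score.
#' @param missense_mean Mean impact of all scored missense mutations.
#' @return An object of class `impact_bounds`.
#' @seealso [estimate_impact_bounds()], [assign_impact_score()]
#' @export
impact_bounds <- function(ma_max, ma_min, missense_mean) {
  stopifnot(is.numeric(ma_max), is.numeric(ma_min), is.numeric(missense_mean),
            ma_min >= 0, ma_min <= missense_mean, missense_mean <= ma_max)
  structure(list(ma_max = ma_max, ma_min = ma_min,
                 missense_mean = missense_mean),
            class = "impact_bounds")
}

#' Estimate impact bounds from a cohort of mutation records
#'
#' Bounds are taken from the impact scores present on the records: the
#' maximum and minimum scored impact, and the mean over scored missense
#' mutations.  Defaults are used for a cohort carrying no scores at all.
#'
#' @param records Mutation record data frame (see [read_maf()]).
#' @param default_max,default_min Fallback bounds when no record is scored.
#' @return An [impact_bounds()] object.
#' @export
estimate_impact_bounds <- function(records, default_max = 5, default_min = 0) {
  scored <- records$impact[!is.na(records$impact)]
  mis <- records$impact[records$variant_class == "missense" &
                          !is.na(records$impact)]
  if (length(scored) == 0L)
    return(impact_bounds(default_max, default_min,
                         (default_max + default_min) / 2))
  mmean <- if (length(mis) > 0L) mean(mis) else mean(scored)
  impact_bounds(max(scored), min(scored), mmean)
}

#' Apply the impact scoring rule to mutation records
#'
#' Vectorized over records: indel/nonsense/splice-site mutations receive
#' `ma_max`, silent mutations `ma_min`, scored missense mutations keep their
#' score, unscored missense mutations receive the cohort missense mean, and
#' class `other` returns `NA` (a skip marker, not a score).
#'
#' @param records Mutation record data frame.
#' @param bounds An [impact_bounds()] object.
#' @return Numeric vector of impact scores (`NA` for skipped records).
#' @export
assign_impact_score <- function(records, bounds) {
  stopifnot(inherits(bounds, "impact_bounds"))
  cls <- records$variant_class
  score <- rep(NA_real_, length(cls))
  score[cls %in% c("indel", "nonsense", "splice_site")] <- bounds$ma_max
  score[cls == "silent"] <- bounds$ma_min
  mis <- cls == "missense"
  score[mis] <- ifelse(is.na(records$impact[mis]), bounds$missense_mean,
                       records$impact[mis])
  score
}

#' Build the paired non-synonymous/synonymous mutation matrix
#'
#' For gene \eqn{i} and sample \eqn{j}, each impact entry is the number of
#' mutated bases weighted by the mutation's functional impact score, divided
#' by the gene's total covered bases:
#' \deqn{M_{ij} = \sum_k b_k \cdot s_k / \mathrm{cov}(i)}
#' accumulated separately over non-synonymous (missense, nonsense, indel,
#' splice-site) and synonymous (silent) mutations.  Point mutations contribute
#' one base; indels contribute their recorded length when available, else one.
#' Raw per-cell mutation counts are kept alongside for the coverage and
#' exclusivity statistics.
#'
#' @param records Mutation record data frame.
#' @param coverage Named numeric vector, gene -> covered bases (all positive).
#' @param bounds An [impact_bounds()] object; defaults to
#'   [estimate_impact_bounds()] on `records`.
#' @param samples Ordered sample universe; defaults to the sorted distinct
#'   samples present in `records`.  Pass the full cohort sample list when
#'   some samples carry no mutations.
#' @param genes Ordered gene universe; defaults to `names(coverage)`.
#' @return An object of class `mutation_matrix` with elements `genes`,
#'   `samples`, `nsy`, `sy` (impact matrices), `nsy_counts`, `sy_counts`
#'   (raw event counts) and `bounds`.
#' @export
build_matrix <- function(records, coverage,
                         bounds = estimate_impact_bounds(records),
                         samples = NULL, genes = NULL) {
  if (is.null(genes)) genes <- names(coverage)
  if (is.null(samples)) samples <- sort(unique(records$sample))
  missing_cov <- setdiff(unique(records$gene), names(coverage))
  if (length(missing_cov) > 0L)
    stop("data error: mutated gene(s) missing from coverage table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  if (any(coverage[unique(records$gene)] <= 0))
    stop("data error: non-positive covered bases for a mutated gene",
         call. = FALSE)

  n <- length(genes); m <- length(samples)
  score <- assign_impact_score(records, bounds)
  keep <- !is.na(score) & records$gene %in% genes & records$sample %in% samples
  bases <- if ("bases" %in% names(records)) records$bases else rep(1, nrow(records))
  rec <- records[keep, , drop = FALSE]
  score <- score[keep]; bases <- bases[keep]

  gi <- factor(rec$gene, levels = genes)
  sj <- factor(rec$sample, levels = samples)
  is_sy <- rec$variant_class == "silent"
  w <- bases * score / unname(coverage[rec$gene])

  acc <- function(values, rows) {
    mat <- matrix(0, n, m, dimnames = list(genes, samples))
    if (any(rows)) {
      t <- tapply(values[rows], list(gi[rows], sj[rows]), sum, default = 0)
      mat[rownames(t), colnames(t)] <- t
    }
    mat
  }
  structure(list(genes = genes, samples = samples,
                 nsy = acc(w, !is_sy), sy = acc(w, is_sy),
                 nsy_counts = acc(rep(1, length(w)), !is_sy),
                 sy_counts = acc(rep(1, length(w)), is_sy),
                 bounds = bounds),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("<mutation_matrix> ", length(x$genes), " genes x ", length(x$samples),
      " samples; ", sum(x$nsy_counts), " non-synonymous and ",
      sum(x$sy_counts), " synonymous events\n", sep = "")
  invisible(x)
}

.check_gene <- function(mat, gene) {
  if (!gene %in% mat$genes)
    stop("unknown gene: ", gene, call. = FALSE)
}

#' Per-gene Mutation Factor
#'
#' \deqn{MF_i = \frac{N_i^{NSY}}{\max(N_i^{SY},1)} \cdot
#'       \frac{1}{m}\sum_j (M_{ij}^{NSY} - M_{ij}^{SY})}
#' the contrast between non-synonymous and synonymous mutation impact averaged
#' over all samples, weighted by the ratio of non-synonymous to synonymous
#' event counts (the denominator guarded at one for genes with no synonymous
#' mutations).
#'
#' @param mat A `mutation_matrix` from [build_matrix()].
#' @param gene Gene symbol.
#' @return The gene's mutation factor (zero for an unmutated gene).
#' @seealso [mutation_factors()] for the whole-cohort vector.
#' @export
mutation_factor <- function(mat, gene) {
  .check_gene(mat, gene)
  mutation_factors(mat)[[gene]]
}

#' Mutation Factor for every gene in the matrix
#'
#' @param mat A `mutation_matrix` from [build_matrix()].
#' @return Named numeric vector of mutation factors over `mat$genes`.
#' @export
mutation_factors <- function(mat) {
  w <- rowSums(mat$nsy_counts) / pmax(rowSums(mat$sy_counts), 1)
  w * rowMeans(mat$nsy - mat$sy)
}
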