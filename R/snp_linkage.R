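#' Load GWAS SNPs and apply the association threshold
#'
#' Rows with association p above `p_threshold` are dropped; duplicates by
#' (chromosome, position) are collapsed keeping the smallest p.
#'
#' @param x data.frame or TSV path with header columns `rsid`, `chrom`,
#'   `pos`, `p` (and optionally `trait`).
#' @param p_threshold Association threshold (default 1e-6).
#' @return data.frame `rsid,chrom,pos,p,trait,provenance` with
#'   `provenance = "index"`.
#' @export
load_and_filter_snps <- function(x, p_threshold = 1e-6) {
  if (is.character(x)) x <- utils::read.table(x, header = TRUE, sep = "\t",
                                              stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "chrom", "pos", "p") %in% names(x)))
  if (!"trait" %in% names(x)) x$trait <- "trait"
  x <- x[x$p <= p_threshold, , drop = FALSE]
  x <- dedupe_by_position(x)
  x$provenance <- if (nrow(x)) "index" else character(0)
  rownames(x) <- NULL
  x[, c("rsid", "chrom", "pos", "p", "trait", "provenance")]
}

## collapse duplicate (chrom, pos), keeping the smallest p
dedupe_by_position <- function(x) {
  if (!nrow(x)) return(x)
  x <- x[order(x$chrom, x$pos, x$p), , drop = FALSE]
  x[!duplicated(x[, c("chrom", "pos")]), , drop = FALSE]
}

#' Expand index SNPs with LD proxies
#'
#' Proxies at `r2 >= r2_min` are appended with provenance `"LD-proxy"`,
#' inheriting the index SNP's trait and p; the union is position-deduped
#' (index records win over proxies at the same position).
#'
#' @param index_snps Output of [load_and_filter_snps()].
#' @param ld_table data.frame `index_rsid,proxy_rsid,chrom,pos,r2`
#'   (an external LD lookup is never performed).
#' @param r2_min LD threshold (default 0.8).
#' @return Combined deduped SNP data.frame.
#' @export
expand_ld <- function(index_snps, ld_table, r2_min = 0.8) {
  if (is.null(ld_table) || !nrow(ld_table)) return(index_snps)
  keep <- ld_table$r2 >= r2_min & ld_table$index_rsid %in% index_snps$rsid
  prox <- ld_table[keep, , drop = FALSE]
  if (!nrow(prox)) return(index_snps)
  m <- match(prox$index_rsid, index_snps$rsid)
  prox_df <- data.frame(rsid = prox$proxy_rsid, chrom = prox$chrom,
                        pos = prox$pos, p = index_snps$p[m],
                        trait = index_snps$trait[m],
                        provenance = "LD-proxy",
                        index_rsid = prox$index_rsid, stringsAsFactors = FALSE)
  if (!"index_rsid" %in% names(index_snps))
    index_snps$index_rsid <- index_snps$rsid
  out <- rbind(index_snps, prox_df)
  ## stable dedupe: index records sort ahead of proxies at equal position
  out <- out[order(out$chrom, out$pos, out$provenance != "index", out$p), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link SNPs to genes through significant promoter interactions
#'
#' A link (SNP, gene) is emitted when the SNP's bin and the gene's promoter
#' bin form a significant interaction. SNP and promoter sharing one bin are
#' excluded, as are pairs closer than `min_dist_bins`: near the diagonal,
#' contact frequency is dominated by polymer proximity and the
#' distance-stratified background is least reliable, so promoter-proximal
#' SNPs are better served by nearest-gene annotation than by interaction
#' evidence. SNPs in fully masked bins yield no links, with a warning.
#'
#' @param snps SNP data.frame (`rsid,chrom,pos[,trait]`).
#' @param sig Significant-interaction table from
#'   [significant_interactions()]; only `significant` rows are used.
#' @param genes [gene_models()] output.
#' @param bt The 10-kb [bin_table()] of the interaction calls.
#' @param mask Optional per-bin validity flags for the masked-SNP warning.
#' @param sample Label recorded with each link (default `"sample1"`).
#' @param min_dist_bins Minimum SNP-bin-to-promoter-bin separation for a
#'   link (default 5, i.e. 50 kb at 10-kb resolution).
#' @return data.frame `rsid,index_rsid,gene,trait,sample,snp_bin,
#'   promoter_bin,interaction_p,distance_bp`; `index_rsid` traces LD proxies
#'   back to their index SNP (equal to `rsid` for index SNPs).
#' @export
link_genes <- function(snps, sig, genes, bt, mask = NULL,
                       sample = "sample1", min_dist_bins = 5L) {
  sig <- sig[sig$significant, , drop = FALSE]
  out <- data.frame(rsid = character(), index_rsid = character(),
                    gene = character(),
                    trait = character(), sample = character(),
                    snp_bin = integer(), promoter_bin = integer(),
                    interaction_p = numeric(), distance_bp = numeric(),
                    stringsAsFactors = FALSE)
  if (!nrow(snps)) return(out)
  snps <- snps[snps$chrom == bt$chrom & snps$pos >= 0 &
                 snps$pos < bt$chrom_length, , drop = FALSE]
  if (!nrow(snps)) return(out)
  sb <- bin_index(bt, snps$pos)
  if (!is.null(mask) && any(!mask[sb + 1L]))
    warning(sum(!mask[sb + 1L]), " SNP(s) in masked bins yield no links")
  pb <- promoter_bins(genes, bt)
  key <- paste(pmin(sig$i, sig$j), pmax(sig$i, sig$j))
  for (s in seq_len(nrow(snps))) {
    for (g in seq_len(nrow(genes))) {
      if (is.na(pb[g]) || abs(pb[g] - sb[s]) < min_dist_bins) next
      m <- match(paste(min(sb[s], pb[g]), max(sb[s], pb[g])), key)
      if (is.na(m)) next
      out[nrow(out) + 1L, ] <- list(
        snps$rsid[s],
        if ("index_rsid" %in% names(snps)) snps$index_rsid[s] else snps$rsid[s],
        genes$gene[g],
        if ("trait" %in% names(snps)) snps$trait[s] else NA_character_,
        sample, sb[s], pb[g], sig$p[m],
        abs(sb[s] - pb[g]) * bt$resolution)
    }
  }
  out
}

#' Per-trait gene-set unions and overlap counts across regions
#'
#' Merges SNP-linked genes over regions for each trait, then reports
#' per-trait set sizes, all pairwise intersection counts, the k-way
#' intersection and per-trait exclusive counts.
#'
#' @param links Link table from [link_genes()] with columns `trait`, `gene`
#'   (region/sample already merged in, or pass rbind-ed per-region tables).
#' @return list(`gene_sets` named list, `sizes`, `pairwise` matrix,
#'   `k_way_intersection`, `exclusive`).
#' @export
disorder_set_ops <- function(links) {
  stopifnot(all(c("trait", "gene") %in% names(links)))
  gene_sets <- lapply(split(links$gene, links$trait), unique)
  traits <- names(gene_sets)
  k <- length(traits)
  pw <- matrix(0L, k, k, dimnames = list(traits, traits))
  for (a in seq_len(k)) for (b in seq_len(k))
    pw[a, b] <- length(intersect(gene_sets[[a]], gene_sets[[b]]))
  kway <- if (k) Reduce(intersect, gene_sets) else character(0)
  excl <- vapply(seq_len(k), function(a)
    length(setdiff(gene_sets[[a]],
                   unlist(gene_sets[-a], use.names = FALSE))), integer(1))
  names(excl) <- traits
  list(gene_sets = gene_sets,
       sizes = vapply(gene_sets, length, integer(1)),
       pairwise = pw, k_way_intersection = kway, exclusive = excl)
}

#' SNP density per bin
#'
#' @param snps SNP data.frame (`chrom,pos`).
#' @param bt A [bin_table()].
#' @return Integer SNP count per bin; sums to the number of SNPs on the
#'   chromosome.
#' @export
snp_density <- function(snps, bt) {
  snps <- snps[snps$chrom == bt$chrom & snps$pos >= 0 &
                 snps$pos < bt$chrom_length, , drop = FALSE]
  out <- integer(bt$n_bins)
  if (nrow(snps)) {
    tb <- table(bin_index(bt, snps$pos))
    out[as.integer(names(tb)) + 1L] <- as.integer(tb)
  }
  out
}
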