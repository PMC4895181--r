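#' Sweep interval set
#'
#' A set of genomic intervals (chromosome, start bp, end bp), 1-based and
#' inclusive at both ends, with a label and a source tag. Used both for
#' called sweep regions and for intervals imported from published scans.
#'
#' @param chrom integer chromosome codes
#' @param start,end interval bounds in bp, 1-based inclusive, `start <= end`
#' @param label interval labels (recycled)
#' @param source provenance tag (recycled)
#' @param ... further per-interval columns (e.g. `n_snps`)
#' @return data.frame of class `sweep_set`
#' @export
sweep_set <- function(chrom, start, end, label = "", source = "", ...) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end < start)) stop("interval end < start")
  df <- data.frame(chrom = as.integer(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep_len(as.character(label), length(chrom)),
                   source = rep_len(as.character(source), length(chrom)),
                   ..., stringsAsFactors = FALSE)
  class(df) <- c("sweep_set", "data.frame")
  df
}

#' Merge overlapping intervals within a sweep set
#'
#' Intervals on the same chromosome that overlap or touch (closed-interval
#' convention) are collapsed into one; labels of merged members are joined.
#'
#' @param x a [sweep_set()]
#' @return merged `sweep_set`, ordered by chromosome and start
#' @export
merge_sweep_set <- function(x) {
  if (nrow(x) == 0) return(x)
  x <- x[order(x$chrom, x$start, x$end), ]
  out <- list()
  cur <- x[1, ]
  for (i in seq_len(nrow(x))[-1]) {
    r <- x[i, ]
    if (r$chrom == cur$chrom && r$start <= cur$end) {
      cur$end <- max(cur$end, r$end)
      if (nzchar(r$label) && !identical(r$label, cur$label)) {
        cur$label <- paste(cur$label, r$label, sep = ";")
      }
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- r
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sweep_set", "data.frame")
  res
}

#' Call sweep regions from per-SNP P-values
#'
#' Collapses maximal runs of significant SNPs (`p < alpha`) on one
#' chromosome into regions, allowing up to `max_gap_snps` interleaved
#' non-significant SNPs inside a run. Region bounds are the positions of the
#' flanking significant SNPs; the number of significant SNPs per region is
#' reported.
#'
#' @param p per-SNP P-values, in `snp_map` order
#' @param snp_map data.frame with `snp`, `chrom`, `pos`
#' @param alpha significance threshold (default 0.05)
#' @param max_gap_snps maximum non-significant SNPs bridged inside a region
#'   (default 2)
#' @param source provenance tag stored on the returned set
#' @return a [sweep_set()] with an `n_snps` column (possibly empty)
#' @export
call_regions <- function(p, snp_map, alpha = 0.05, max_gap_snps = 2,
                         source = "scan") {
  stopifnot(length(p) == nrow(snp_map))
  empty <- sweep_set(integer(0), numeric(0), numeric(0), n_snps = integer(0))
  ord <- order(snp_map$chrom, snp_map$pos)
  regions <- list()
  for (ch in unique(snp_map$chrom[ord])) {
    sel <- ord[snp_map$chrom[ord] == ch]
    sig <- which(p[sel] < alpha)
    if (!length(sig)) next
    run_start <- sig[1]
    prev <- sig[1]
    n_in <- 1L
    flush <- function(a, b, n) {
      regions[[length(regions) + 1L]] <<- data.frame(
        chrom = ch, start = snp_map$pos[sel[a]], end = snp_map$pos[sel[b]],
        n_snps = n)
    }
    for (s in sig[-1]) {
      if (s - prev - 1L <= max_gap_snps) {
        prev <- s
        n_in <- n_in + 1L
      } else {
        flush(run_start, prev, n_in)
        run_start <- s
        prev <- s
        n_in <- 1L
      }
    }
    flush(run_start, prev, n_in)
  }
  if (!length(regions)) return(empty)
  df <- do.call(rbind, regions)
  sweep_set(df$chrom, df$start, df$end,
            label = sprintf("chr%d:%.3f-%.3fMb", df$chrom, df$start / 1e6,
                            df$end / 1e6),
            source = source, n_snps = df$n_snps)
}

#' Windows around outlier SNP positions
#'
#' Each outlier SNP becomes a closed interval `[pos - w, pos + w]`, clipped
#' to chromosome bounds when lengths are supplied. Overlapping windows are
#' merged per set unless `merge = FALSE` (one window per outlier, used when
#' co-localizations are counted per outlier SNP).
#'
#' @param chrom,pos outlier chromosome codes and bp positions
#' @param w half-window in bp (default 1e6, i.e. 1 Mb)
#' @param chrom_lengths optional bp lengths indexed by chromosome code
#' @param merge merge overlapping windows (default TRUE)
#' @param label,source passed to [sweep_set()]
#' @return a [sweep_set()]
#' @export
snp_windows <- function(chrom, pos, w = 1e6, chrom_lengths = NULL,
                        merge = TRUE, label = "", source = "windows") {
  stopifnot(w > 0, length(chrom) == length(pos))
  start <- pmax(pos - w, 1)
  end <- pos + w
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, chrom_lengths[as.integer(chrom)])
  }
  ss <- sweep_set(chrom, start, end, label = label, source = source)
  if (merge) merge_sweep_set(ss) else ss
}

#' Count set-2 intervals overlapping set 1
#'
#' Number of `set2` intervals that intersect at least one `set1` interval on
#' the same chromosome. Intervals are closed, so touching boundaries count
#' as an overlap of at least one bp.
#'
#' @param set1,set2 [sweep_set()] objects in the same coordinate convention
#' @param chromosomes optional universe of valid chromosome codes; an
#'   interval on an unknown chromosome raises an error
#' @return integer count (between 0 and `nrow(set2)`)
#' @export
count_overlaps <- function(set1, set2, chromosomes = NULL) {
  if (!is.null(chromosomes)) {
    bad <- setdiff(c(set1$chrom, set2$chrom), chromosomes)
    if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(set1) == 0 || nrow(set2) == 0) return(0L)
  hit <- vapply(seq_len(nrow(set2)), function(i) {
    any(set1$chrom == set2$chrom[i] &
          set1$start <= set2$end[i] & set1$end >= set2$start[i])
  }, logical(1))
  sum(hit)
}

# Map bp intervals to [first SNP >= start, last SNP <= end] index ranges on
# the chromosome-ordered map. Intervals containing no SNP are dropped.
intervals_to_index <- function(ss, map_ord) {
  n <- nrow(ss)
  s_idx <- integer(n)
  e_idx <- integer(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    j <- which(map_ord$chrom == ss$chrom[i] &
                 map_ord$pos >= ss$start[i] & map_ord$pos <= ss$end[i])
    if (length(j)) {
      s_idx[i] <- j[1]
      e_idx[i] <- j[length(j)]
      keep[i] <- TRUE
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " interval(s) contained no SNP and were dropped")
  }
  list(start = s_idx[keep], end = e_idx[keep], n_dropped = sum(!keep))
}

#' Circular permutation test of interval-set overlap
#'
#' Tests whether the observed number of `set2` intervals overlapping `set1`
#' exceeds chance. The genome is circularized by concatenating chromosomes
#' in order; both interval sets are converted to SNP-index ranges on the
#' map. Each of `n_perm` replicates draws a single uniform shift `d` in
#' `1..M` (`M` = number of SNPs), rotates every `set2` interval by `d` SNPs
#' with wrap-around, and recounts the overlaps in index space (an overlap is
#' a shared SNP index). The bootstrapped P-value is the proportion of
#' replicates whose overlap count strictly exceeds the observed count
#' ("exceeds" read literally); `plus_one = TRUE` instead reports
#' `(b + 1) / (n_perm + 1)`.
#'
#' @param set1 reference intervals (e.g. sweeps from earlier studies)
#' @param set2 query intervals (the sweeps whose placement is randomized)
#' @param snp_map data.frame with `snp`, `chrom`, `pos` defining the map
#' @param n_perm number of random shifts (default 10000)
#' @param seed integer seed
#' @param plus_one use the (b+1)/(N+1) estimator (default FALSE)
#' @return list of class `permutation_result`: `observed`, `counts`
#'   (length `n_perm`), `p_value`, `n_perm`, `seed`, `n_dropped`
#' @export
circular_permutation_test <- function(set1, set2, snp_map, n_perm = 10000,
                                      seed = 1, plus_one = FALSE) {
  stopifnot(n_perm >= 1)
  chroms <- unique(snp_map$chrom)
  bad <- setdiff(c(set1$chrom, set2$chrom), chroms)
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  map_ord <- snp_map[order(snp_map$chrom, snp_map$pos), ]
  M <- nrow(map_ord)
  i1 <- intervals_to_index(set1, map_ord)
  i2 <- intervals_to_index(set2, map_ord)
  occ <- logical(M)
  for (k in seq_along(i1$start)) occ[i1$start[k]:i1$end[k]] <- TRUE
  cs <- c(0, cumsum(occ))
  range_hit <- function(s, e) {
    # s, e: equal-length index vectors, s <= e guaranteed after unwrap
    cs[e + 1] - cs[s] > 0
  }
  count_at_shift <- function(d) {
    s <- (i2$start + d - 1L) %% M + 1L
    e <- (i2$end + d - 1L) %% M + 1L
    wrap <- s > e
    n_hit <- 0L
    if (any(!wrap)) n_hit <- sum(range_hit(s[!wrap], e[!wrap]))
    if (any(wrap)) {
      n_hit <- n_hit + sum(range_hit(s[wrap], rep(M, sum(wrap))) |
                             range_hit(rep(1L, sum(wrap)), e[wrap]))
    }
    n_hit
  }
  observed <- count_at_shift(0L)
  set.seed(seed)
  d <- sample.int(M, n_perm, replace = TRUE)
  counts <- vapply(d, count_at_shift, integer(1))
  b <- sum(counts > observed)
  p <- if (plus_one) (b + 1) / (n_perm + 1) else b / n_perm
  structure(
    list(observed = observed, counts = counts, p_value = p, n_perm = n_perm,
         seed = seed, n_dropped = i1$n_dropped + i2$n_dropped),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("circular permutation test:", x$n_perm, "shifts\n")
  cat("observed overlaps:", x$observed,
      " bootstrapped P =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Read / write sweep sets as TSV
#'
#' BED-like TSV with columns chrom, start, end, label, source; coordinates
#' are 1-based and inclusive (unlike 0-based half-open BED). Set
#' `from_bed = TRUE` / `to_bed = TRUE` to convert on the way in / out.
#'
#' @param path file path
#' @param from_bed,to_bed convert between 0-based half-open and the 1-based
#'   inclusive convention used here
#' @param x a [sweep_set()]
#' @return `read_sweep_set`: a [sweep_set()]; `write_sweep_set`: `path`,
#'   invisibly
#' @export
read_sweep_set <- function(path, from_bed = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (from_bed) df$start <- df$start + 1
  if (is.null(df$label)) df$label <- ""
  if (is.null(df$source)) df$source <- ""
  sweep_set(df$chrom, df$start, df$end, label = df$label, source = df$source)
}

#' @rdname read_sweep_set
#' @export
write_sweep_set <- function(x, path, to_bed = FALSE) {
  df <- as.data.frame(x)
  if (to_bed) df$start <- df$start - 1
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
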