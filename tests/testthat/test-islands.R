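mini_map <- function(n = 100, chr = 1L, spacing = 5e4) {
  data.frame(chr = chr, snp_id = sprintf("c%d_%d", chr, seq_len(n)), cm = 0,
             pos = seq(1e6, by = spacing, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("snp_occurrence counts covering individuals once each", {
  snps <- mini_map(50)
  # every one of 10 individuals carries the identical segment
  segs <- do.call(rbind, lapply(1:10, function(i)
    data.frame(fid = "F", iid = sprintf("i%d", i), chr = 1L,
               start_bp = snps$pos[10], end_bp = snps$pos[20], n_snps = 11L,
               length_bp = snps$pos[20] - snps$pos[10] + 1)))
  prof <- snp_occurrence(segs, snps, 10)
  expect_equal(prof$percent[10:20], rep(100, 11))
  expect_equal(prof$percent[-(10:20)], rep(0, 39))

  # zero segments: all-zero profile
  empty <- snp_occurrence(segs[0, ], snps, 10)
  expect_true(all(empty$count == 0))

  # overlapping segments of one individual count once
  two <- rbind(
    data.frame(fid = "F", iid = "i1", chr = 1L, start_bp = snps$pos[5],
               end_bp = snps$pos[15], n_snps = 11L,
               length_bp = snps$pos[15] - snps$pos[5] + 1),
    data.frame(fid = "F", iid = "i1", chr = 1L, start_bp = snps$pos[10],
               end_bp = snps$pos[25], n_snps = 16L,
               length_bp = snps$pos[25] - snps$pos[10] + 1))
  prof2 <- snp_occurrence(two, snps, 5)
  expect_true(all(prof2$count <= 1))

  expect_error(snp_occurrence(
    data.frame(fid = "F", iid = "i1", chr = 9L, start_bp = 1, end_bp = 2,
               n_snps = 1L, length_bp = 2), snps, 5), "absent")
})

test_that("occurrence equals a per-SNP membership recount on random input", {
  set.seed(61)
  snps <- rbind(mini_map(60, 1L), mini_map(40, 2L))
  for (rep in 1:10) {
    segs <- do.call(rbind, lapply(1:8, function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      chr <- sample(1:2, k, replace = TRUE)
      lo <- sample.int(3e6, k) + 1e6
      data.frame(fid = "F", iid = sprintf("i%d", i), chr = chr,
                 start_bp = lo, end_bp = lo + sample.int(2e6, k),
                 n_snps = 15L, length_bp = 1)
    }))
    if (is.null(segs)) next
    prof <- snp_occurrence(segs, snps, 8)
    brute <- vapply(seq_len(nrow(snps)), function(j) {
      covering <- segs$chr == snps$chr[j] & segs$start_bp <= snps$pos[j] &
        segs$end_bp >= snps$pos[j]
      length(unique(segs$iid[covering]))
    }, numeric(1))
    expect_equal(prof$count, brute)
    # double-counting identity: total occurrence = sum over (iid, segment
    # union) of SNPs inside -- here segments per individual may overlap, so
    # compare against the per-individual union recount
    expect_equal(sum(prof$count), sum(brute))
  }
})

test_that("top-percent selection keeps ties at the cutoff", {
  snps <- mini_map(100)
  prof <- data.frame(chr = 1L, snp_id = snps$snp_id, pos = snps$pos,
                     count = 100:1, percent = 100:1)
  sel <- select_top_percent(prof, 1)
  expect_equal(sum(sel$selected), 1)
  expect_equal(sel$cutoff, 100)

  prof$count <- c(rep(95, 5), seq(90, by = -1, length.out = 95))
  prof$percent <- prof$count
  sel5 <- select_top_percent(prof, 1)  # 5 SNPs tied at the maximum
  expect_equal(sum(sel5$selected), 5)

  zero <- prof
  zero$count <- 0
  expect_warning(selz <- select_top_percent(zero, 1), "all-zero")
  expect_false(any(selz$selected))

  # sort-based oracle on random profiles
  set.seed(62)
  for (rep in 1:20) {
    prof$count <- sample(0:30, 100, replace = TRUE)
    if (all(prof$count == 0)) prof$count[1] <- 1
    pct <- sample(c(1, 2, 5), 1)
    sel <- select_top_percent(prof, pct)
    k <- ceiling(pct / 100 * 100)
    expect_gte(sum(sel$selected), k)
    expect_true(min(prof$count[sel$selected]) >=
                  max(c(prof$count[!sel$selected], -Inf)))
    expect_equal(sel$cutoff, sort(prof$count, decreasing = TRUE)[k])
  }
})

test_that("islands merge selected SNPs by gap and size rules", {
  snps <- mini_map(100)  # 50 kb spacing
  sel <- rep(FALSE, 100)
  sel[11:30] <- TRUE
  isl <- build_islands(sel, snps, max_island_gap_kb = 1000,
                       min_island_snps = 3)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$n_snp, 20)
  expect_equal(isl$start_bp, snps$pos[11])
  expect_equal(isl$end_bp, snps$pos[30])
  expect_equal(isl$start_mb, round(snps$pos[11] / 1e6, 2))

  # two clusters 5 Mb apart become two islands
  snps2 <- rbind(mini_map(50), mini_map(50, spacing = 5e4))
  snps2$pos[51:100] <- snps2$pos[50] + 5e6 + seq(0, by = 5e4, length.out = 50)
  snps2$chr <- 1L
  snps2$snp_id <- sprintf("s%d", 1:100)
  sel2 <- rep(FALSE, 100)
  sel2[c(10:20, 60:70)] <- TRUE
  expect_equal(nrow(build_islands(sel2, snps2, 1000, 3)), 2)

  # islands below min_island_snps are dropped
  sel3 <- rep(FALSE, 100)
  sel3[c(5, 6, 50, 51)] <- TRUE
  expect_equal(nrow(build_islands(sel3, snps, 1000, 3)), 0)

  # brute-force interval-merge oracle on random selections
  set.seed(63)
  snps3 <- rbind(mini_map(60), mini_map(60, chr = 2L))
  for (rep in 1:20) {
    sel <- runif(120) < 0.15
    isl <- build_islands(sel, snps3, 500, 2)
    # oracle: walk the selected SNPs and merge neighbours <= 500 kb apart
    idx <- which(sel)
    groups <- list()
    for (i in idx) {
      g <- length(groups)
      if (g > 0) {
        last <- groups[[g]][length(groups[[g]])]
        same <- snps3$chr[last] == snps3$chr[i] &&
          snps3$pos[i] - snps3$pos[last] <= 5e5
      } else same <- FALSE
      if (same) groups[[g]] <- c(groups[[g]], i) else
        groups[[g + 1]] <- i
    }
    keep <- Filter(function(g) length(g) >= 2, groups)
    expect_equal(nrow(isl), length(keep))
    if (length(keep)) {
      expect_equal(isl$start_bp, vapply(keep, function(g)
        snps3$pos[g[1]], numeric(1))[order(vapply(keep, function(g)
          snps3$chr[g[1]] * 1e10 + snps3$pos[g[1]], numeric(1)))])
      expect_equal(isl$n_snp, lengths(keep)[order(vapply(keep, function(g)
        snps3$chr[g[1]] * 1e10 + snps3$pos[g[1]], numeric(1)))])
    }
  }
})

test_that("annotation assigns genes by >= 1 bp interval overlap", {
  isl <- data.frame(chr = 13L, n_snp = 19L, start_bp = 50590000,
                    end_bp = 51890000, start_mb = 50.59, end_mb = 51.89)
  genes <- data.frame(chr = c(13L, 13L, 2L), start = c(50900000, 60000000, 1),
                      end = c(51200000, 60500000, 1e6),
                      gene = c("BMP2", "FAR", "OTHER"),
                      stringsAsFactors = FALSE)
  ann <- annotate_islands(isl, genes)
  expect_equal(ann$genes[[1]], "BMP2")
  expect_equal(ann$genes_str, "BMP2")

  none <- annotate_islands(data.frame(chr = 20L, n_snp = 3L, start_bp = 1,
                                      end_bp = 2, start_mb = 0, end_mb = 0),
                           genes)
  expect_equal(none$genes[[1]], character(0))
  expect_equal(annotate_islands(isl, NULL)$genes_str, "")

  # all-pairs overlap oracle on random islands and genes
  set.seed(64)
  islands <- data.frame(chr = sample(1:3, 15, replace = TRUE),
                        n_snp = 5L,
                        start_bp = sample.int(5e7, 15))
  islands$end_bp <- islands$start_bp + sample.int(5e6, 15)
  islands$start_mb <- round(islands$start_bp / 1e6, 2)
  islands$end_mb <- round(islands$end_bp / 1e6, 2)
  g50 <- data.frame(chr = sample(1:3, 50, replace = TRUE),
                    start = sample.int(5e7, 50))
  g50$end <- g50$start + sample.int(2e6, 50)
  g50$gene <- sprintf("G%02d", 1:50)
  ann <- annotate_islands(islands, g50)
  for (i in 1:15) {
    manual <- g50$gene[g50$chr == islands$chr[i] &
                         pmax(g50$start, islands$start_bp[i]) <=
                         pmin(g50$end, islands$end_bp[i])]
    expect_setequal(ann$genes[[i]], manual)
  }
})

test_that("bundled synthetic gene fixtures agree across dialects", {
  bed <- system.file("extdata", "synthetic_ovine_genes.bed",
                     package = "rohscan")
  gff <- system.file("extdata", "synthetic_ovine_genes.gff3",
                     package = "rohscan")
  gb <- read_gene_intervals(bed, "bed")
  gg <- read_gene_intervals(gff, "gff3")
  expect_equal(gb, gg)
  expect_true("BMP2" %in% gb$gene)
})

test_that("occurrence plot renders to a file for edge-case profiles", {
  d <- withr::local_tempdir()
  snps <- mini_map(40)
  flat <- data.frame(chr = snps$chr, snp_id = snps$snp_id, pos = snps$pos,
                     count = 0L, percent = 0)
  p1 <- file.path(d, "flat.pdf")
  occurrence_plot(flat, NULL, p1)
  expect_true(file.exists(p1) && file.size(p1) > 0)

  peak <- flat
  peak$count[10:20] <- 8L
  peak$percent <- 100 * peak$count / 10
  sel <- select_top_percent(peak, 10)
  p2 <- file.path(d, "peak.pdf")
  occurrence_plot(peak, sel, p2, n_individuals = 10)
  expect_true(file.exists(p2) && file.size(p2) > 0)
  # the planted peak is the selected set
  expect_true(all(which(sel$selected) %in% 10:20))
})
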