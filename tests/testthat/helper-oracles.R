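# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / naive DP, never by calling the package's
# own fast paths.

# naive Smith-Waterman score by full DP in R
bf_sw_score <- function(q, r, match = 5, mismatch = -4, gap = -8) {
  nq <- nchar(q); nr <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  H <- matrix(0, nq + 1, nr + 1)
  best <- 0
  for (i in 2:(nq + 1)) {
    for (j in 2:(nr + 1)) {
      sub <- if (qs[i - 1] == rs[j - 1] && qs[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, H[i - 1, j] + gap,
                     H[i, j - 1] + gap)
      best <- max(best, H[i, j])
    }
  }
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# exhaustive mean richness and mean Shannon entropy over all subsamples of
# size m drawn without replacement from the individuals behind abundance x
bf_subsample_diversity <- function(x, m) {
  individuals <- rep(seq_along(x), x)
  subs <- utils::combn(length(individuals), m)
  rich <- numeric(ncol(subs)); ent <- numeric(ncol(subs))
  for (k in seq_len(ncol(subs))) {
    tab <- table(individuals[subs[, k]])
    p <- as.numeric(tab) / m
    rich[k] <- length(tab)
    ent[k] <- -sum(p * log(p))
  }
  list(mean_richness = mean(rich), mean_entropy = mean(ent))
}

# naive IUPAC site scan returning 1-based match starts
iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
bf_iupac_sites <- function(pattern, subject) {
  pl <- nchar(pattern); sl <- nchar(subject)
  pat <- strsplit(pattern, "")[[1]]; sub <- strsplit(subject, "")[[1]]
  hits <- integer(0)
  if (sl < pl) return(hits)
  for (s in 1:(sl - pl + 1)) {
    ok <- TRUE
    for (p in 1:pl) {
      if (!grepl(sub[s + p - 1], iupac_expand[[pat[p]]], fixed = TRUE)) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# hand OLS via the normal equations
bf_ols <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - ym)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# small test reference: two families, a germline-identical pair, one
# pseudogene, one J set and a C -- built in code, no fixtures on disk
tiny_reference <- function() {
  set.seed(99)
  base1 <- paste0(rand_seq(57), "TGTGCC")          # anchor TGT at offset 57
  base2 <- paste0(rand_seq(57), "TGTACC")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(setdiff(seq_along(ch), 58:60), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  va1 <- base1; va2 <- mut(base1, 5); va3 <- va2   # va2/va3 identical
  vb1 <- base2; vb2 <- mut(base2, 5)
  j1 <- paste0(rand_seq(21), "TTT", rand_seq(12))  # anchor TTT at offset 21
  j2 <- paste0(rand_seq(21), "TTT", rand_seq(12))
  cseq <- rand_seq(60)
  tibble::tibble(
    id = c("VA.1", "VA.2", "VA.3", "VB.1", "VB.2", "VB.3", "J1", "J2", "C"),
    segment_type = c(rep("V", 6), "J", "J", "C"),
    family = c(rep("VA", 3), rep("VB", 3), NA, NA, NA),
    family_index = c(1:3, 1:3, NA, NA, NA),
    functional_status = c(rep("functional", 5), "pseudogene",
                          "functional", "functional", "functional"),
    anchor_offset = c(rep(57L, 5), NA, 21L, 21L, NA),
    rss = c(rep(paste0("CACAGTG", strrep("A", 23), "ACAAAAACC"), 5), NA,
            NA, NA, NA),
    locus_start = seq(0L, by = 200L, length.out = 9),
    locus_end = seq(0L, by = 200L, length.out = 9) +
      nchar(c(va1, va2, va3, vb1, vb2, mut(base2, 5), j1, j2, cseq)),
    motif_block = NA_character_,
    note = NA_character_,
    sequence = c(va1, va2, va3, vb1, vb2, mut(base2, 5), j1, j2, cseq)
  )
}
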