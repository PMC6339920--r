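# Straight-line recomputation of the whole inference chain, written as an
# independent oracle: explicit loops, no calls into the package's internals.
brute_force_infer <- function(db, profile, pec, split = TRUE) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  taxa <- profile$taxa
  nt <- nrow(taxa)
  units <- colnames(db$unit_copies)
  ssu <- rep(NA_real_, nt)
  copies <- matrix(0, nt, length(units), dimnames = list(NULL, units))
  matched <- logical(nt)
  for (i in seq_len(nt)) {
    sel <- rep(TRUE, nrow(db$genomes))
    for (r in ranks) {
      q <- taxa[[r]][i]
      if (nzchar(q)) sel <- sel & (tolower(db$genomes[[r]]) == tolower(q))
      if (identical(r, taxa$deepest_rank[i])) break
    }
    if (any(sel)) {
      matched[i] <- TRUE
      ssu[i] <- mean(db$genomes$ssu_copies[sel])
      copies[i, ] <- colMeans(db$unit_copies[sel, , drop = FALSE])
    }
  }
  corr <- profile$abundance[matched, , drop = FALSE] / ssu[matched]
  for (s in seq_len(ncol(corr)))
    if (sum(corr[, s]) > 0) corr[, s] <- corr[, s] / sum(corr[, s])
  copies <- copies[matched, , drop = FALSE]

  unit_ab <- matrix(0, length(units), ncol(corr),
                    dimnames = list(units, colnames(corr)))
  for (u in seq_along(units)) for (s in seq_len(ncol(corr)))
    unit_ab[u, s] <- sum(corr[, s] * copies[, u])

  mult <- rep(0, length(units)); names(mult) <- units
  for (m in db$pathways$member_units) mult[m] <- mult[m] + 1
  mult[mult == 0] <- 1

  np <- nrow(db$pathways)
  com_raw <- matrix(0, np, ncol(corr),
                    dimnames = list(db$pathways$pathway_id, colnames(corr)))
  for (p in seq_len(np)) {
    mem <- db$pathways$member_units[[p]]
    for (s in seq_len(ncol(corr))) {
      ndet <- sum(unit_ab[mem, s] > 0)
      if (ndet >= 1 && ndet / length(mem) >= pec / 100) {
        tot <- 0
        for (u in mem) tot <- tot + unit_ab[u, s] / (if (split) mult[u] else 1)
        com_raw[p, s] <- tot
      }
    }
  }
  com_rel <- com_raw
  for (s in seq_len(ncol(corr)))
    if (sum(com_raw[, s]) > 0) com_rel[, s] <- com_raw[, s] / sum(com_raw[, s])

  ico_raw <- matrix(0, np, ncol(corr),
                    dimnames = list(db$pathways$pathway_id, colnames(corr)))
  for (t in seq_len(nrow(corr))) {
    for (p in seq_len(np)) {
      mem <- db$pathways$member_units[[p]]
      det <- mem[copies[t, mem] > 0]
      if (length(det) >= 1 && length(det) / length(mem) >= pec / 100) {
        w <- 0
        for (u in det) w <- w + copies[t, u] / (if (split) mult[u] else 1)
        for (s in seq_len(ncol(corr)))
          ico_raw[p, s] <- ico_raw[p, s] + corr[t, s] * w
      }
    }
  }
  list(corrected = corr, unit_ab = unit_ab, com_raw = com_raw,
       com_rel = com_rel, ico_raw = ico_raw)
}
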