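# literal transcription of the target-site rules, written independently of
# the implementation: states over miRNA positions 1..L, G:U weighs 0.5
rule_oracle <- function(mirna, site, duplex_energy, perfect_energy,
                        strict = TRUE, gu_adjacent = FALSE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wobble <- c(G = "U", U = "G")
  m <- strsplit(gsub("T", "U", toupper(mirna)), "")[[1]]
  s <- rev(strsplit(gsub("T", "U", toupper(site)), "")[[1]])
  L <- length(m)
  state <- vapply(seq_len(L), function(i) {
    if (comp[m[i]] == s[i]) "WC"
    else if (!is.na(wobble[m[i]]) && wobble[m[i]] == s[i]) "GU"
    else "MM"
  }, character(1))
  w <- ifelse(state == "MM", 1, ifelse(state == "GU", 0.5, 0))
  adj <- vapply(seq_len(L - 1), function(i) {
    both <- state[i] != "WC" && state[i + 1] != "WC"
    if (gu_adjacent) both
    else both && (state[i] == "MM" || state[i + 1] == "MM")
  }, logical(1))
  runs3 <- any(vapply(seq_len(max(L - 2, 0)), function(i) {
    adj[i] && adj[i + 1]
  }, logical(1)))
  ok <- sum(w) <= 4 &&                                    # (a)
    !runs3 &&                                             # (b)
    !any(adj[2:11]) &&                                    # (c)
    state[10] == "WC" && state[11] == "WC" &&             # (d)
    sum(w[1:12]) <= 2.5 &&                                # (e)
    duplex_energy / perfect_energy >= 0.75                # (f)
  if (strict) ok <- ok && sum(w) <= 2
  ok
}

stringi_rev <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

mutate_site <- function(site, k) {
  chars <- strsplit(site, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "U"),
                                            chars[p]), 1)
  paste(chars, collapse = "")
}
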