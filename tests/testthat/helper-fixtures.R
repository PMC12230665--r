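# shared fixtures, built in code at test time

local_kb_dir <- function(seed = 1, n_per_source = 10,
                         env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_toy_kb(dir, seed = seed, n_per_source = n_per_source)
  dir
}

load_toy_kb <- function(dir) suppressWarnings(load_kb_dir(dir))

# independent dynamic-programming Levenshtein distance (test oracle)
dp_edit_distance <- function(a, b) {
  a <- strsplit(tolower(a), "")[[1]]
  b <- strsplit(tolower(b), "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[n + 1, m + 1]
}

# brute-force per-record therapy matcher (test oracle): re-decides every
# rule independently of the package's vectorized implementation
brute_force_match <- function(variant, kb, annotation = NULL) {
  v_exon <- if (is.null(annotation)) NA_integer_ else
    oncotherapyr:::aa_pos_to_exon(annotation, variant$aa_pos)
  labels <- character(nrow(kb))
  for (k in seq_len(nrow(kb))) {
    if (kb$biomarker_gene[k] != variant$gene) { labels[k] <- NA; next }
    s <- trimws(kb$biomarker_spec[k])
    m_ex <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))[[1]]
    m_po <- regmatches(s, regexec("^([A-Z])([0-9]+)$", s))[[1]]
    m_xn <- regmatches(tolower(s),
                       regexec("^exon ([0-9]+)( mutations?)?$", tolower(s)))[[1]]
    lab <- NA_character_
    if (length(m_ex) > 0 && as.integer(m_ex[3]) == variant$aa_pos) {
      lab <- if (m_ex[4] == variant$alt_aa) "exact" else "same_pos_other_aa"
    } else if (length(m_po) > 0 && as.integer(m_po[3]) == variant$aa_pos) {
      lab <- "same_pos_any"
    } else if (!is.na(v_exon)) {
      spec_exon <- if (length(m_xn) > 0) {
        as.integer(m_xn[2])
      } else if (length(m_ex) > 0) {
        oncotherapyr:::aa_pos_to_exon(annotation, as.integer(m_ex[3]))
      } else if (length(m_po) > 0) {
        oncotherapyr:::aa_pos_to_exon(annotation, as.integer(m_po[3]))
      } else NA_integer_
      if (!is.na(spec_exon) && spec_exon == v_exon) lab <- "same_exon"
    }
    if (is.na(lab) &&
        grepl("^((oncogenic )?mutations?|any mutation( in gene)?|alteration)$",
              tolower(s)) || (is.na(lab) && !nzchar(s))) {
      lab <- "gene_level"
    }
    labels[k] <- lab
  }
  labels
}

# independently encoded ACMG combining-rules oracle
acmg_oracle <- function(codes) {
  strength <- c(PVS1 = "vs", PS1 = "s", PM1 = "m", PM2 = "m", PM5 = "m",
                PP3 = "p", PP5 = "p", BA1 = "ba", BS1 = "bs", BP4 = "bp",
                BP6 = "bp")
  st <- strength[codes]
  vs <- sum(st == "vs"); s <- sum(st == "s"); m <- sum(st == "m")
  p <- sum(st == "p")
  ba <- sum(st == "ba"); bs <- sum(st == "bs"); bp <- sum(st == "bp")
  if ((vs + s + m + p) > 0 && (ba + bs + bp) > 0) return("vus")
  # pathogenic rules (Ia-d, II, IIIa-c)
  if (vs >= 1 && (s >= 1 || m >= 2 || (m == 1 && p >= 1) || p >= 2)) return("pathogenic")
  if (s >= 2) return("pathogenic")
  if (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4))) return("pathogenic")
  # likely pathogenic rules (i-vi)
  if (vs == 1 && m == 1) return("likely_pathogenic")
  if (s == 1 && (m == 1 || m == 2)) return("likely_pathogenic")
  if (s == 1 && p >= 2) return("likely_pathogenic")
  if (m >= 3) return("likely_pathogenic")
  if (m == 2 && p >= 2) return("likely_pathogenic")
  if (m == 1 && p >= 4) return("likely_pathogenic")
  # benign / likely benign
  if (ba >= 1 || bs >= 2) return("benign")
  if ((bs == 1 && bp >= 1) || bp >= 2) return("likely_benign")
  "vus"
}

acmg_label_rank <- function(x) {
  match(x, c("benign", "likely_benign", "vus", "likely_pathogenic",
             "pathogenic"))
}

# place a lone atom tibble for geometry tests
lone_atom <- function(x = 0, y = 0, z = 0, element = "S", radius = 1.9,
                      res_index = 1L) {
  tibble::tibble(res_index = res_index, resname = "CYS", aa = "C",
                 atom = "SG", element = element, x = x, y = y, z = z,
                 radius = radius, confidence = 90)
}

as_structure <- function(atoms) oncotherapyr:::atoms_to_structure(atoms)
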