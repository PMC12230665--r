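#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_dbl map_int map_lgl pmap imap keep
#' @importFrom stringr str_detect str_match str_trim str_squish str_to_lower
#'   str_replace_all str_split str_sub str_to_upper str_to_title
NULL

# path to a packaged reference table
otr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "oncotherapyr")
  if (!nzchar(path)) abort(paste0("packaged file not found: ", file))
  path
}

otr_error <- function(msg, class, ...) {
  abort(msg, class = c(class, "oncotherapyr_error"), ...)
}

# one-letter <-> three-letter amino-acid codes (incl. stop)
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V","*")
AA3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile",
         "Leu","Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val","Ter")

aa3_to_1 <- function(x) {
  idx <- match(str_to_upper(x), str_to_upper(AA3))
  out <- AA1[idx]
  out[str_to_upper(x) == "*"] <- "*"
  out
}

aa1_to_3 <- function(x) AA3[match(str_to_upper(x), AA1)]

is_aa1 <- function(x) x %in% AA1

# normalize free-text labels for comparison keys: trim, case-fold,
# collapse internal whitespace
normalize_label <- function(x) str_squish(str_to_lower(str_trim(x)))

vec_norm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vec_norm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
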