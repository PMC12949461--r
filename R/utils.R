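`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic string hash
#'
#' Polynomial rolling hash over UTF-8 bytes, reduced modulo 2^31. Used to
#' derive reproducible pseudo-random streams keyed by arbitrary strings
#' (seed, source name, entity key) without touching R's global RNG state.
#'
#' @param ... character or numeric fragments; concatenated with a field
#'   separator before hashing.
#' @return a single non-negative integer-valued double < 2^31.
#' @keywords internal
strHash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 17
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  h
}

# uniform [0,1) deviate from a hashed key; stable across platforms
hashUnit <- function(...) {
  strHash(...) / 2147483647
}

trimws2 <- function(x) trimws(x, which = "both")

#' Split a CURIE-style token into namespace and accession
#'
#' Tokens of the form "NS:acc" are split at the first colon; anything else
#' is returned with an NA namespace. Namespaces are uppercased, accessions
#' kept verbatim.
#' @keywords internal
splitCurie <- function(x) {
  has <- grepl(":", x, fixed = TRUE)
  ns <- ifelse(has, toupper(sub(":.*$", "", x)), NA_character_)
  acc <- ifelse(has, sub("^[^:]*:", "", x), x)
  data.frame(namespace = ns, accession = acc, stringsAsFactors = FALSE)
}

canonicalKey <- function(namespace, accession) {
  paste0(toupper(namespace), ":", accession)
}

stopf <- function(fmt, ..., class = "ckg_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# stable sort helper: radix method gives locale-independent C ordering
sortC <- function(x) {
  if (is.null(x) || !length(x)) return(character())
  sort(x, method = "radix")
}

orderC <- function(...) order(..., method = "radix")
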