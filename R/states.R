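#' @useDynLib mdcnv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Copy-number state alphabet shared with PennCNV-style callers:
# 1 = homozygous deletion (CN0), 2 = hemizygous deletion (CN1),
# 3 = diploid (CN2), 5 = single copy gain (CN3), 6 = two copy gain (CN4).
.SYMBOLS <- c(1L, 2L, 3L, 5L, 6L)
.SYMBOL_CN <- c(`1` = 0L, `2` = 1L, `3` = 2L, `5` = 3L, `6` = 4L)
.CN_SYMBOL <- c(`0` = 1L, `1` = 2L, `2` = 3L, `3` = 5L, `4` = 6L)

#' Copy-number state symbols
#'
#' The five copy-number state symbols used throughout the package, mapping to
#' copy numbers 0--4 as \code{1->0, 2->1, 3->2, 5->3, 6->4}.
#'
#' @return Integer vector of the five symbols.
#' @export
trio_symbols <- function() .SYMBOLS

.check_symbol <- function(s) {
  s <- as.integer(s)
  if (any(!s %in% .SYMBOLS))
    stop("invalid copy-number state symbol: ",
         paste(setdiff(s, .SYMBOLS), collapse = ", "))
  s
}

#' Convert between state symbols and copy numbers
#'
#' @param symbol integer state symbol(s) in \{1, 2, 3, 5, 6\}.
#' @param cn integer copy number(s) in 0--4.
#' @return Integer vector of copy numbers (`symbol_cn`) or symbols
#'   (`cn_symbol`).
#' @export
symbol_cn <- function(symbol) {
  unname(.SYMBOL_CN[as.character(.check_symbol(symbol))])
}

#' @rdname symbol_cn
#' @export
cn_symbol <- function(cn) {
  cn <- as.integer(cn)
  if (any(cn < 0L | cn > 4L)) stop("copy number must be in 0..4")
  unname(.CN_SYMBOL[as.character(cn)])
}

#' Enumerate the trio copy-number state space
#'
#' All father-by-mother-by-offspring triplets over the five state symbols,
#' minus the four biologically implausible combinations in which both parents
#' are homozygous null (copy number 0) while the offspring carries one or more
#' copies. 121 states remain.
#'
#' @return A list with components `states` (character vector of 121
#'   three-character codes such as "332", lexicographic order) and `excluded`
#'   (the 4 removed codes).
#' @examples
#' length(enumerate_states()$states)  # 121
#' @export
enumerate_states <- function() {
  grid <- expand.grid(o = .SYMBOLS, m = .SYMBOLS, f = .SYMBOLS,
                      KEEP.OUT.ATTRS = FALSE)
  codes <- sort(paste0(grid$f, grid$m, grid$o))
  implausible <- substr(codes, 1, 1) == "1" & substr(codes, 2, 2) == "1" &
    substr(codes, 3, 3) != "1"
  list(states = codes[!implausible], excluded = codes[implausible])
}

# A parent with copy number c carries ceiling(c/2) and floor(c/2) copies on
# its two homologs and transmits either with probability 1/2.
.transmit <- function(cn) c(cn %/% 2L, cn - cn %/% 2L)

#' Mendelian transmission probability of an offspring copy number
#'
#' Probability that the offspring has copy number `o_cn` given parental copy
#' numbers, under independent transmission of one homolog per parent. The
#' offspring copy number is the sum of the transmitted copies, capped at 4
#' (copy numbers above 4 are pooled into the two-copy-gain state).
#'
#' @param f_cn,m_cn,o_cn integer copy numbers in 0--4.
#' @return Probability in \[0, 1\].
#' @examples
#' mendelian_prob(2, 2, 2)  # 1: both diploid parents transmit one copy
#' mendelian_prob(2, 2, 1)  # 0: unreachable, i.e. de novo
#' @export
mendelian_prob <- function(f_cn, m_cn, o_cn) {
  stopifnot(length(f_cn) == 1L, length(m_cn) == 1L, length(o_cn) == 1L)
  cns <- as.integer(c(f_cn, m_cn, o_cn))
  if (any(cns < 0L | cns > 4L)) stop("copy number must be in 0..4")
  tf <- .transmit(cns[1L])
  tm <- .transmit(cns[2L])
  sums <- pmin(outer(tf, tm, `+`), 4L)
  mean(sums == cns[3L])
}

#' Mendelian transmission table
#'
#' The full 25 x 5 table of offspring copy-number probabilities for every
#' parental copy-number pair. Rows are named "f:m" for father/mother copy
#' numbers; columns are offspring copy numbers 0--4. The table is the default
#' transmission model; a replacement table of the same shape can be passed to
#' [offspring_conditional()] and [call_trio()].
#'
#' @return A 25 x 5 numeric matrix with rows summing to 1.
#' @export
mendelian_table <- function() {
  tab <- matrix(0, 25L, 5L,
                dimnames = list(paste(rep(0:4, each = 5L), rep(0:4, 5L),
                                      sep = ":"),
                                as.character(0:4)))
  for (f in 0:4) for (m in 0:4) for (o in 0:4)
    tab[paste(f, m, sep = ":"), as.character(o)] <- mendelian_prob(f, m, o)
  tab
}

#' Conditional probability of the offspring state given the parents
#'
#' Integrates the Mendelian transmission model against a latent indicator for
#' Mendelian inheritance: with probability `p_mendelian` the offspring copy
#' number follows [mendelian_prob()]; otherwise it is uniform over the five
#' states.
#'
#' @param f,m,o state symbols in \{1, 2, 3, 5, 6\}.
#' @param p_mendelian prior probability of Mendelian transmission
#'   (default `1 - 1.5e-6`).
#' @param table optional replacement 25 x 5 transmission table as from
#'   [mendelian_table()].
#' @return Probability of the offspring symbol given the parental symbols.
#' @export
offspring_conditional <- function(f, m, o, p_mendelian = 1 - 1.5e-6,
                                  table = NULL) {
  stopifnot(p_mendelian >= 0, p_mendelian <= 1)
  cns <- symbol_cn(c(f, m, o))
  pm <- if (is.null(table)) mendelian_prob(cns[1L], cns[2L], cns[3L])
        else table[paste(cns[1L], cns[2L], sep = ":"), as.character(cns[3L])]
  p_mendelian * pm + (1 - p_mendelian) / 5
}

#' Parental state transition probability between adjacent segments
#'
#' 1/2 if the state is unchanged, 1/8 otherwise, so each row of the implied
#' 5 x 5 transition matrix sums to one.
#'
#' @param prev,cur state symbols.
#' @return Transition probability.
#' @export
parent_transition_prob <- function(prev, cur) {
  prev <- .check_symbol(prev)
  cur <- .check_symbol(cur)
  ifelse(prev == cur, 0.5, 0.125)
}

#' Initial state probability
#'
#' Uniform over the five copy-number states.
#'
#' @param symbol state symbol(s).
#' @return 0.2 for every valid symbol.
#' @export
initial_state_prob <- function(symbol) {
  .check_symbol(symbol)
  rep(0.2, length(symbol))
}

#' Is a trio state de novo?
#'
#' A trio state is de novo when the offspring copy number is unreachable by
#' Mendelian transmission from the parental copy numbers, i.e.
#' [mendelian_prob()] is zero.
#'
#' @param state character vector of three-character state codes (e.g. "332").
#' @return Logical vector.
#' @examples
#' is_de_novo("332")  # TRUE: diploid parents, hemizygous offspring
#' is_de_novo("232")  # FALSE: paternally inherited deletion
#' @export
is_de_novo <- function(state) {
  vapply(as.character(state), function(code) {
    if (nchar(code) != 3L) stop("state code must have three symbols: ", code)
    cns <- symbol_cn(as.integer(strsplit(code, "")[[1L]]))
    mendelian_prob(cns[1L], cns[2L], cns[3L]) == 0
  }, logical(1L), USE.NAMES = FALSE)
}
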