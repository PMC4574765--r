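# Shared fixtures and independent oracles. The oracles are written straight
# from the textbook definitions and never call the package functions they
# check.

minimal_kgml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:hsa00001" org="hsa" number="00001" title="Mini" image="mini.png">\n',
    '<entry id="10" name="hsa:1356 hsa:1359" type="gene">',
    '<graphics name="CPA3, MC-CPA" type="rectangle" x="100" y="50" width="46" height="17"/></entry>\n',
    '<entry id="11" name="hsa:183" type="gene">',
    '<graphics name="AGT" type="rectangle" x="200" y="50" width="46" height="17"/></entry>\n',
    '<relation entry1="10" entry2="11" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>\n',
    "</pathway>\n")
}

# 2 genes x 4 samples, groups A (reference) / B, hand-checkable values
tiny_dataset <- function() {
  values <- matrix(c(1, 3, 5, 7,
                     2, 2, 2, 2),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), c("s1", "s2", "s3", "s4")))
  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  expression_dataset(values, groups, reference = "A")
}

# fetcher stub that counts invocations; optionally fails on every call
counting_fetcher <- function(fail = FALSE) {
  env <- new.env()
  env$count <- 0L
  env$fetch <- function(path) {
    env$count <- env$count + 1L
    if (fail) stop("network disabled by test stub")
    charToRaw(paste0("payload-for:", path))
  }
  env
}

# fetcher serving an in-memory map of resource path -> content
map_fetcher <- function(resources) {
  env <- new.env()
  env$count <- 0L
  env$fetch <- function(path) {
    env$count <- env$count + 1L
    if (is.null(resources[[path]])) stop("no such resource: ", path)
    val <- resources[[path]]
    if (is.raw(val)) val else charToRaw(val)
  }
  env
}

# Benjamini-Hochberg step-up rule, written from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * n / j), mapped back to input order.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  s <- p[ord]
  val <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, s[i] * n / i)
    val[i] <- running
  }
  out <- numeric(n)
  out[ord] <- val
  out
}

# Welch two-sample t from the closed-form formula, two-sided p from the
# t-distribution survival function with Welch-Satterthwaite df.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df))
}

# graphs compare equal on everything the round-trip must preserve
expect_same_graph <- function(a, b) {
  expect_identical(a$pathway_id, b$pathway_id)
  expect_identical(a$nodes$entry_id, b$nodes$entry_id)
  expect_identical(a$nodes$node_type, b$nodes$node_type)
  expect_identical(a$nodes$label, b$nodes$label)
  expect_equal(a$nodes$x, b$nodes$x)
  expect_equal(a$nodes$y, b$nodes$y)
  expect_equal(a$nodes$width, b$nodes$width)
  expect_equal(a$nodes$height, b$nodes$height)
  expect_identical(lapply(a$nodes$kegg_ids, as.character),
                   lapply(b$nodes$kegg_ids, as.character))
  expect_identical(lapply(a$nodes$member_ids, as.character),
                   lapply(b$nodes$member_ids, as.character))
  expect_identical(a$edges$source, b$edges$source)
  expect_identical(a$edges$target, b$edges$target)
  expect_identical(a$edges$kind, b$edges$kind)
  expect_identical(a$edges$subtype, b$edges$subtype)
}

json_of <- function(res) jsonlite::fromJSON(res$json, simplifyVector = FALSE)
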