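#!/usr/bin/env Rscript
# Command-line entry point for the anlcsim package.
#
# Usage:
#   Rscript scripts/anlcsim.R <subcommand> [options]
#
# Subcommands:
#   simulate        --config <yaml> [--out <dir>]
#   retrieve        --stack <stack.tif> [--config <yaml>] [--out <dir>]
#   compare-designs --config <yaml> [--out <dir>]
#   droplet         --config <yaml> [--out <file>]
#   fixtures        --out <dir> [--seed <int>]

suppressPackageStartupMessages(library(anlcsim))

parse_args <- function(args) {
  if (length(args) < 1) stop("missing subcommand", call. = FALSE)
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      stop("options take the form --key value", call. = FALSE)
    }
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  list(cmd = cmd, opts = opts)
}

main <- function() {
  a <- parse_args(commandArgs(trailingOnly = TRUE))
  o <- a$opts
  switch(a$cmd,
    "simulate" = cli_simulate(o$config, o$out),
    "retrieve" = cli_retrieve(o$stack, o$config, o$out),
    "compare-designs" = {
      cmp <- cli_compare_designs(o$config, o$out)
      print(cmp)
    },
    "droplet" = cli_droplet(o$config, o$out),
    "fixtures" = generate_fixtures(o$out %||% "fixtures",
                                   as.integer(o$seed %||% "1")),
    stop("unknown subcommand: ", a$cmd, call. = FALSE)
  )
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

if (sys.nframe() == 0) main()
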