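test_that("ELU matches its closed form, is continuous at 0 and monotone", {
  expect_equal(elu(2), 2)
  expect_equal(elu(0), 0)
  expect_equal(elu(-1, alpha = 1), exp(-1) - 1, tolerance = 1e-9)
  expect_equal(elu(-1), -0.632121, tolerance = 1e-6)
  expect_error(elu(1, alpha = 0), "alpha")
  for (a in c(0.5, 1, 2)) {
    # continuity at 0
    expect_lt(abs(elu(1e-9, a) - elu(-1e-9, a)), 1e-8)
    # monotone increasing on a grid
    g <- elu(seq(-5, 5, by = 0.01), a)
    expect_true(all(diff(g) > 0))
  }
  # shape preservation
  m <- matrix(c(-1, 0, 1, 2), 2)
  expect_equal(dim(elu(m)), dim(m))
})

# analytic gradients for a single-branch net, mirroring one training step
net_grads <- function(net, x, y) {
  fw <- nn_forward(net, list(x = x), with_cache = TRUE)
  n <- length(y)
  dout <- matrix(2 * (fw$out - y) / n, n, 1)
  dcur <- dout
  grads_head <- vector("list", length(net$head))
  for (i in rev(seq_along(net$head))) {
    bw <- backward_layer(net$head[[i]], dcur, fw$head_caches[[i]], net$alpha)
    grads_head[i] <- list(bw$grads)
    dcur <- bw$dx
  }
  gb <- backward_stack(net$branches$x, fw$branch_caches$x, dcur, net$alpha)
  list(head = grads_head, branch = gb,
       loss = mean((fw$out - y)^2))
}

test_that("backpropagated gradients match finite differences", {
  withr::with_seed(41, {
    n <- 6; L <- 14
    x <- array(rnorm(n * L), c(n, L, 1))
    y <- rnorm(n)
    layers <- list(layer_conv1d(3, 5), layer_avgpool1d(2), layer_conv1d(2, 3),
                   layer_flatten(), layer_dense(4), layer_dense(1, "linear"))
    net <- build_nn(branches = list(x = layers),
                    input_shapes = list(x = c(L, 1L)),
                    head = list(layer_dense(1L, activation = "linear")),
                    alpha = 1, seed = 5)
    g <- net_grads(net, x, y)
    eps <- 1e-6
    loss_at <- function(net) {
      out <- nn_forward(net, list(x = x))
      mean((out - y)^2)
    }
    # sample parameter entries across layer types (conv, dense, head)
    checks <- list(list(where = "branch", li = 1, slot = "W", idx = c(2, 3)),
                   list(where = "branch", li = 1, slot = "b", idx = 1),
                   list(where = "branch", li = 3, slot = "W", idx = c(5, 2)),
                   list(where = "branch", li = 5, slot = "W", idx = c(5, 3)),
                   list(where = "branch", li = 6, slot = "b", idx = 1),
                   list(where = "head", li = 1, slot = "W", idx = c(1, 1)))
    for (ck in checks) {
      bump <- function(net, d) {
        if (ck$where == "branch") {
          if (length(ck$idx) == 2)
            net$branches$x[[ck$li]][[ck$slot]][ck$idx[1], ck$idx[2]] <-
              net$branches$x[[ck$li]][[ck$slot]][ck$idx[1], ck$idx[2]] + d
          else net$branches$x[[ck$li]][[ck$slot]][ck$idx] <-
              net$branches$x[[ck$li]][[ck$slot]][ck$idx] + d
        } else {
          net$head[[ck$li]][[ck$slot]][ck$idx[1], ck$idx[2]] <-
            net$head[[ck$li]][[ck$slot]][ck$idx[1], ck$idx[2]] + d
        }
        net
      }
      numeric_grad <- (loss_at(bump(net, eps)) - loss_at(bump(net, -eps))) /
        (2 * eps)
      analytic <- if (ck$where == "branch") {
        gr <- g$branch[[ck$li]][[ck$slot]]
        if (length(ck$idx) == 2) gr[ck$idx[1], ck$idx[2]] else gr[ck$idx]
      } else g$head[[ck$li]][[ck$slot]][ck$idx[1], ck$idx[2]]
      expect_equal(analytic, numeric_grad, tolerance = 1e-5)
    }
  })
})

test_that("embedding and 2D-convolution gradients also match finite differences", {
  withr::with_seed(42, {
    n <- 5
    x2d <- array(rnorm(n * 8 * 6), c(n, 8, 6, 1))
    cat <- matrix(sample(1:3, n * 2, TRUE), n, 2)
    num <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    branches <- list(
      grid = list(layer_conv2d(2, c(3, 3)), layer_avgpool2d(2),
                  layer_flatten(), layer_dense(3)),
      meta = list(layer_embedding_concat(c(3L, 3L), c(2L, 2L)),
                  layer_conv1d(2, 3), layer_flatten())
    )
    net <- build_nn(branches, list(grid = c(8L, 6L, 1L),
                                   meta = list(num = 2L)),
                    head = list(layer_dense(1L, activation = "linear")),
                    seed = 6)
    inputs <- list(grid = x2d, meta = list(cat = cat, num = num))
    fw <- nn_forward(net, inputs, with_cache = TRUE)
    dout <- matrix(2 * (fw$out - y) / n, n, 1)
    bw_head <- backward_layer(net$head[[1]], dout, fw$head_caches[[1]], 1)
    off <- fw$branch_widths[["grid"]]
    g_grid <- backward_stack(net$branches$grid, fw$branch_caches$grid,
                             bw_head$dx[, 1:off, drop = FALSE], 1)
    g_meta <- backward_stack(net$branches$meta, fw$branch_caches$meta,
                             bw_head$dx[, (off + 1):ncol(bw_head$dx),
                                        drop = FALSE], 1)
    loss_at <- function(net) mean((nn_forward(net, inputs) - y)^2)
    eps <- 1e-6
    # conv2d weight
    net_p <- net; net_p$branches$grid[[1]]$W[4, 2] <-
      net_p$branches$grid[[1]]$W[4, 2] + eps
    net_m <- net; net_m$branches$grid[[1]]$W[4, 2] <-
      net_m$branches$grid[[1]]$W[4, 2] - eps
    expect_equal(g_grid[[1]]$W[4, 2],
                 (loss_at(net_p) - loss_at(net_m)) / (2 * eps),
                 tolerance = 1e-5)
    # embedding table entry
    net_p <- net; net_p$branches$meta[[1]]$E[[1]][2, 1] <-
      net_p$branches$meta[[1]]$E[[1]][2, 1] + eps
    net_m <- net; net_m$branches$meta[[1]]$E[[1]][2, 1] <-
      net_m$branches$meta[[1]]$E[[1]][2, 1] - eps
    expect_equal(g_meta[[1]]$E[[1]][2, 1],
                 (loss_at(net_p) - loss_at(net_m)) / (2 * eps),
                 tolerance = 1e-5)
  })
})

test_that("network construction enforces shape preconditions", {
  expect_error(build_single_modal(3), "kernel span")
  expect_error(init_layer(layer_conv1d(4, 5), c(4L, 1L)), "smaller than kernel")
  expect_error(init_layer(layer_conv2d(4, c(3, 3)), c(2L, 9L, 1L)),
               "smaller than kernel")
})

test_that("zero input with zero-initialized biases yields zero output", {
  net <- build_single_modal(60, test_cnn_config())
  x <- array(0, c(4, 60, 1))
  expect_equal(as.numeric(nn_forward(net, list(x = x))), rep(0, 4))
})

test_that("single-modal network accepts n x p and returns n x 1", {
  net <- build_single_modal(500, test_cnn_config())
  x <- array(rnorm(3 * 500), c(3, 500, 1))
  out <- nn_forward(net, list(x = x))
  expect_equal(dim(out), c(3, 1))
})
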