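// Masked autoregressive conditional density estimator (MADE with Gaussian
// conditionals) and its atomic, proposal-corrected training loss.
//
// The estimator models q(z | x) = prod_i N(z_i; mu_i(x, z_<i), exp(s_i)^2)
// with a single masked tanh hidden layer. Hidden unit k carries a degree
// d_k in {0, .., Dz-1}; it connects to inputs z_1..z_{d_k} (and to all of
// x), and feeds outputs for dimensions i > d_k. This enforces the
// autoregressive factorization exactly while conditioning every dimension
// on x.
//
// Training minimizes the atomic contrastive loss of sequential neural
// posterior estimation: for a data pair (x_j, z_j) and an atom set
// A_j = {j} U {m_1..m_{M-1}} of parameter candidates,
//   loss_j = -log softmax_{m in A_j} [ log q(z_m | x_j) - log p(z_m) ]
// evaluated at the self atom, which corrects for draws coming from a
// proposal rather than the prior. With fewer than two atoms the loss
// degenerates to the plain negative log-likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double S_MIN = -7.0, S_MAX = 3.0;
static const double LOG_2PI_HALF = 0.91893853320467274178;

struct Net {
  mat W1, Wm, Ws, M1, M2;
  vec b1, bm, bs;
};

static Net as_net(const Rcpp::List& l) {
  Net n;
  n.W1 = Rcpp::as<mat>(l["W1"]); n.b1 = Rcpp::as<vec>(l["b1"]);
  n.Wm = Rcpp::as<mat>(l["Wm"]); n.bm = Rcpp::as<vec>(l["bm"]);
  n.Ws = Rcpp::as<mat>(l["Ws"]); n.bs = Rcpp::as<vec>(l["bs"]);
  n.M1 = Rcpp::as<mat>(l["M1"]); n.M2 = Rcpp::as<mat>(l["M2"]);
  return n;
}

// Forward pass for a block of rows. U is (n x (Dx+Dz)) = [X, Z].
static void forward(const Net& net, const mat& U,
                    mat& H, mat& Mu, mat& S, umat& clamped) {
  mat A1 = U * (net.W1 % net.M1).t();
  A1.each_row() += net.b1.t();
  H = tanh(A1);
  Mu = H * (net.Wm % net.M2).t();
  Mu.each_row() += net.bm.t();
  S = H * (net.Ws % net.M2).t();
  S.each_row() += net.bs.t();
  clamped = (S < S_MIN) + (S > S_MAX);
  S = clamp(S, S_MIN, S_MAX);
}

static vec row_logprob(const mat& Z, const mat& Mu, const mat& S) {
  mat e2s = exp(-2.0 * S);
  mat q = square(Z - Mu) % e2s;
  return -LOG_2PI_HALF * (double)Z.n_cols - sum(S, 1) - 0.5 * sum(q, 1);
}

// [[Rcpp::export]]
arma::vec made_logprob_cpp(Rcpp::List net_l, arma::mat X, arma::mat Z) {
  Net net = as_net(net_l);
  mat U = join_rows(X, Z), H, Mu, S; umat cl;
  forward(net, U, H, Mu, S, cl);
  return row_logprob(Z, Mu, S);
}

// Autoregressive sampling: n draws of z | x. Uses R's RNG so draws are
// reproducible under set.seed().
// [[Rcpp::export]]
arma::mat made_sample_cpp(Rcpp::List net_l, arma::rowvec x, int n) {
  Net net = as_net(net_l);
  int dz = net.Wm.n_rows;
  mat X = repmat(x, n, 1);
  mat Eps(n, dz);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < dz; ++j) Eps(i, j) = R::norm_rand();
  mat Zc(n, dz, fill::zeros), H, Mu, S; umat cl;
  for (int i = 0; i < dz; ++i) {
    mat U = join_rows(X, Zc);
    forward(net, U, H, Mu, S, cl);
    Zc.col(i) = Mu.col(i) + exp(S.col(i)) % Eps.col(i);
  }
  return Zc;
}

struct Grads { mat W1, Wm, Ws; vec b1, bm, bs; };

// Atomic loss and gradient on an expanded batch: row r of (Xe, Ze)
// corresponds to the atom pair (j = r / M, m = r % M); atom 0 of each group
// is the self pair. lpe holds log p(z_m) per row. With M < 2 the plain
// negative log-likelihood over the rows is used.
static double loss_grad(const Net& net, const mat& Xe, const mat& Ze,
                        const vec& lpe, int M, Grads& g) {
  mat U = join_rows(Xe, Ze), H, Mu, S; umat cl;
  forward(net, U, H, Mu, S, cl);
  vec lq = row_logprob(Ze, Mu, S);
  int nrow = Xe.n_rows;
  vec gout(nrow);
  double loss = 0.0;
  int B;
  if (M >= 2) {
    B = nrow / M;
    vec ell = lq - lpe;
    for (int j = 0; j < B; ++j) {
      subview_col<double> e = ell.subvec(j * M, j * M + M - 1);
      double mx = e.max();
      vec w = exp(e - mx);
      double Zs = accu(w);
      loss += -(e(0) - mx - std::log(Zs));
      for (int m = 0; m < M; ++m) gout(j * M + m) = w(m) / Zs;
      gout(j * M) -= 1.0;
    }
  } else {
    B = nrow;
    loss = -accu(lq);
    gout.fill(-1.0);
  }
  // d lq / d mu_i = e^{-2 s_i} (z_i - mu_i);  d lq / d s_i = -1 + e^{-2 s_i}(z_i - mu_i)^2
  mat e2s = exp(-2.0 * S);
  mat R = (Ze - Mu) % e2s;
  mat Gmu = R;  Gmu.each_col() %= gout;
  mat Gs = (square(Ze - Mu) % e2s - 1.0);
  Gs.each_col() %= gout;
  Gs.elem(find(cl > 0)).zeros();

  g.Wm = (Gmu.t() * H) % net.M2;
  g.bm = sum(Gmu, 0).t();
  g.Ws = (Gs.t() * H) % net.M2;
  g.bs = sum(Gs, 0).t();
  mat dH = Gmu * (net.Wm % net.M2) + Gs * (net.Ws % net.M2);
  mat dA = dH % (1.0 - square(H));
  g.W1 = (dA.t() * U) % net.M1;
  g.b1 = sum(dA, 0).t();

  double inv = 1.0 / (double)B;
  g.W1 *= inv; g.b1 *= inv; g.Wm *= inv; g.bm *= inv; g.Ws *= inv; g.bs *= inv;
  return loss * inv;
}

// Exposed for finite-difference gradient checks in the test suite.
// [[Rcpp::export]]
Rcpp::List made_loss_grad_cpp(Rcpp::List net_l, arma::mat Xe, arma::mat Ze,
                              arma::vec lpe, int M) {
  Net net = as_net(net_l);
  Grads g;
  double loss = loss_grad(net, Xe, Ze, lpe, M, g);
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = g.W1, Rcpp::Named("b1") = g.b1,
      Rcpp::Named("Wm") = g.Wm, Rcpp::Named("bm") = g.bm,
      Rcpp::Named("Ws") = g.Ws, Rcpp::Named("bs") = g.bs));
}

static void adam_update(mat& W, mat& mW, mat& vW, const mat& g,
                        double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  mW = b1 * mW + (1.0 - b1) * g;
  vW = b2 * vW + (1.0 - b2) * square(g);
  mat mhat = mW / (1.0 - std::pow(b1, t));
  mat vhat = vW / (1.0 - std::pow(b2, t));
  W -= lr * mhat / (sqrt(vhat) + eps);
}

static int unif_index(int n) {  // uniform integer in [0, n)
  int k;
  do { k = (int)(R::unif_rand() * n); } while (k >= n);
  return k;
}

// Train the estimator with Adam on the cumulative sample set (X: n x Dx,
// Z: n x Dz, logp: n prior log-densities): n_steps updates, each on a
// random minibatch of data pairs with freshly drawn atom sets. A fixed step
// count per round keeps the per-round cost independent of how much the
// cumulative set has grown. Modifies copies; returns updated net, Adam
// state and the per-step loss.
// [[Rcpp::export]]
Rcpp::List made_train_cpp(Rcpp::List net_l, arma::mat X, arma::mat Z,
                          arma::vec logp, int n_steps, int batch,
                          int n_atoms, double lr, Rcpp::List adam_l) {
  Rcpp::RNGScope scope;
  Net net = as_net(net_l);
  Grads m = { Rcpp::as<mat>(adam_l["mW1"]), Rcpp::as<mat>(adam_l["mWm"]),
              Rcpp::as<mat>(adam_l["mWs"]), Rcpp::as<vec>(adam_l["mb1"]),
              Rcpp::as<vec>(adam_l["mbm"]), Rcpp::as<vec>(adam_l["mbs"]) };
  Grads v = { Rcpp::as<mat>(adam_l["vW1"]), Rcpp::as<mat>(adam_l["vWm"]),
              Rcpp::as<mat>(adam_l["vWs"]), Rcpp::as<vec>(adam_l["vb1"]),
              Rcpp::as<vec>(adam_l["vbm"]), Rcpp::as<vec>(adam_l["vbs"]) };
  double t = Rcpp::as<double>(adam_l["t"]);

  int N = X.n_rows;
  int B = std::min(batch, N);
  int M = std::min(n_atoms, N);
  vec step_loss(n_steps, fill::zeros);

  for (int st = 0; st < n_steps; ++st) {
    int rows = (M >= 2) ? B * M : B;
    mat Xe(rows, X.n_cols), Ze(rows, Z.n_cols);
    vec lpe(rows);
    if (M >= 2) {
      std::vector<int> atoms(M);
      for (int jj = 0; jj < B; ++jj) {
        int j = unif_index(N);
        atoms[0] = j;
        for (int a = 1; a < M; ++a) {
          int cand;
          bool dup;
          do {
            cand = unif_index(N);
            dup = false;
            for (int q = 0; q < a; ++q)
              if (atoms[q] == cand) { dup = true; break; }
          } while (dup || cand == j);
          atoms[a] = cand;
        }
        for (int a = 0; a < M; ++a) {
          int r = jj * M + a;
          Xe.row(r) = X.row(j);
          Ze.row(r) = Z.row(atoms[a]);
          lpe(r) = logp(atoms[a]);
        }
      }
    } else {
      for (int jj = 0; jj < B; ++jj) {
        int j = unif_index(N);
        Xe.row(jj) = X.row(j);
        Ze.row(jj) = Z.row(j);
        lpe(jj) = logp(j);
      }
    }
    Grads g;
    double loss = loss_grad(net, Xe, Ze, lpe, (M >= 2) ? M : 1, g);
    if (!std::isfinite(loss))
      Rcpp::stop("non-finite training loss");
    t += 1.0;
    adam_update(net.W1, m.W1, v.W1, g.W1, lr, t);
    adam_update(net.Wm, m.Wm, v.Wm, g.Wm, lr, t);
    adam_update(net.Ws, m.Ws, v.Ws, g.Ws, lr, t);
    mat gb1(g.b1), gbm(g.bm), gbs(g.bs);
    mat nb1(net.b1), nbm(net.bm), nbs(net.bs);
    mat mb1(m.b1), mbm(m.bm), mbs(m.bs), vb1(v.b1), vbm(v.bm), vbs(v.bs);
    adam_update(nb1, mb1, vb1, gb1, lr, t);
    adam_update(nbm, mbm, vbm, gbm, lr, t);
    adam_update(nbs, mbs, vbs, gbs, lr, t);
    net.b1 = nb1.col(0); m.b1 = mb1.col(0); v.b1 = vb1.col(0);
    net.bm = nbm.col(0); m.bm = mbm.col(0); v.bm = vbm.col(0);
    net.bs = nbs.col(0); m.bs = mbs.col(0); v.bs = vbs.col(0);
    step_loss(st) = loss;
  }

  Rcpp::List net_out = Rcpp::List::create(
    Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
    Rcpp::Named("Wm") = net.Wm, Rcpp::Named("bm") = net.bm,
    Rcpp::Named("Ws") = net.Ws, Rcpp::Named("bs") = net.bs,
    Rcpp::Named("M1") = net.M1, Rcpp::Named("M2") = net.M2);
  Rcpp::List adam_out = Rcpp::List::create(
    Rcpp::Named("t") = t,
    Rcpp::Named("mW1") = m.W1, Rcpp::Named("vW1") = v.W1,
    Rcpp::Named("mb1") = m.b1, Rcpp::Named("vb1") = v.b1,
    Rcpp::Named("mWm") = m.Wm, Rcpp::Named("vWm") = v.Wm,
    Rcpp::Named("mbm") = m.bm, Rcpp::Named("vbm") = v.bm,
    Rcpp::Named("mWs") = m.Ws, Rcpp::Named("vWs") = v.Ws,
    Rcpp::Named("mbs") = m.bs, Rcpp::Named("vbs") = v.bs);
  return Rcpp::List::create(Rcpp::Named("net") = net_out,
                            Rcpp::Named("adam") = adam_out,
                            Rcpp::Named("step_loss") = step_loss);
}
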