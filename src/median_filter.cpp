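#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 2-D median filter with reflection (mirror-without-repeat) edge padding.
// window must be odd; each output pixel is the median of the window x
// window neighbourhood of the reflected image.
// [[Rcpp::export]]
NumericMatrix cppMedianFilter(NumericMatrix img, int window) {
    if (window < 1 || window % 2 == 0)
        stop("window must be an odd integer >= 1");
    int H = img.nrow(), W = img.ncol(), h = window / 2;
    NumericMatrix out(H, W);
    std::vector<double> buf(window * window);

    auto reflect = [](int i, int n) {
        // mirror about the edges: ... 2 1 0 | 0 1 2 ... (repeat-edge mirror)
        if (n == 1) return 0;
        while (i < 0 || i >= n) {
            if (i < 0) i = -i - 1;
            if (i >= n) i = 2 * n - i - 1;
        }
        return i;
    };

    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            int m = 0;
            for (int dj = -h; dj <= h; ++dj) {
                int jj = reflect(j + dj, W);
                for (int di = -h; di <= h; ++di) {
                    int ii = reflect(i + di, H);
                    buf[m++] = img(ii, jj);
                }
            }
            std::nth_element(buf.begin(), buf.begin() + m / 2,
                             buf.begin() + m);
            out(i, j) = buf[m / 2];
        }
    }
    return out;
}
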