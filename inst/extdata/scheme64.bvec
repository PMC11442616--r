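0.000000 0.411018 0.919893 -0.948342 0.308518 0.673721 -0.592975 -0.048602 0.987130 0.756522 -0.812167 -0.985661 -0.099364 -0.791786 0.199732 0.834420 0.511548 0.950124 -0.587776 -0.931380 -0.293362 -0.375203 0.870798 0.485775 0.173111 -0.883582 -0.598373 0.886229 0.655776 -0.698273 0.649807 -0.872705 -0.072354 0.806474 -0.777701 -0.093704 0.226303 0.392341 -0.421718 -0.319956 0.722401 -0.723775 0.388259 0.132968 -0.547019 0.715932 -0.680445 -0.510684 0.569733 0.430660 -0.191289 0.042184 0.553125 -0.242297 -0.496790 0.094343 -0.420874 0.245194 0.435030 -0.271843 0.287105 -0.058563 -0.222255 -0.021786 0.140312
0.000000 0.911627 -0.391876 -0.316071 -0.949935 0.734035 0.800546 -0.992229 -0.102063 -0.637412 -0.562041 -0.039805 0.978903 0.571041 0.955233 0.504322 -0.822376 0.180804 -0.767938 0.252221 -0.910731 0.876109 -0.365467 0.808628 -0.921067 -0.292384 0.672378 -0.063601 -0.591219 -0.535019 0.591467 0.019662 0.869387 0.305815 0.368949 -0.854033 0.823475 -0.748489 -0.724981 0.730397 -0.320610 -0.223755 0.622079 -0.720531 0.471204 0.062433 0.125319 -0.459165 0.367181 -0.500034 -0.629547 0.655675 -0.181425 0.524674 -0.115507 -0.484882 0.240508 0.410151 0.121433 -0.351574 -0.226183 0.325431 0.030875 -0.201545 0.085327
0.000000 0.000655 0.015163 0.027332 0.049402 0.085402 0.086643 0.114539 0.123114 0.146221 0.156507 0.163977 0.178540 0.216765 0.218261 0.222268 0.249032 0.254114 0.254539 0.262517 0.290702 0.302748 0.328855 0.331880 0.348811 0.365780 0.435726 0.458861 0.469487 0.475573 0.477406 0.487851 0.488805 0.506041 0.508978 0.511711 0.520265 0.534633 0.544571 0.603447 0.612655 0.652751 0.679906 0.680555 0.691909 0.695373 0.722004 0.726890 0.735243 0.751331 0.753046 0.753864 0.813104 0.816094 0.860150 0.869476 0.874655 0.878440 0.892190 0.895822 0.930813 0.943751 0.974500 0.979237 0.986424
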