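case,compression_pct,force_real_n,force_membrane_n,error_printed_pct
1,43.4,30.745,25.891,15.8
2,31.8,246.73,189.44,23.2
3,29.4,172.90,129.37,25.2
4,33.5,96.938,92.763,4.3
5,31.9,155.68,126.13,19.0
6,30.1,45.653,41.435,9.2
7,41.1,54.858,46.273,15.6
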