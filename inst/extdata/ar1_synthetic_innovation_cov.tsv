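1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783	0.03019738342	0.02351774586	0.01831563889	0.01426423391	0.01110899654	0.008651695203
0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783	0.03019738342	0.02351774586	0.01831563889	0.01426423391	0.01110899654
0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783	0.03019738342	0.02351774586	0.01831563889	0.01426423391
0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783	0.03019738342	0.02351774586	0.01831563889
0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783	0.03019738342	0.02351774586
0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783	0.03019738342
0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837	0.03877420783
0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121	0.04978706837
0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862	0.06392786121
0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246	0.08208499862
0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832	0.1053992246
0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435	0.1353352832
0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601	0.1737739435
0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969	0.2231301601
0.03019738342	0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412	0.2865047969
0.02351774586	0.03019738342	0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527	0.3678794412
0.01831563889	0.02351774586	0.03019738342	0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597	0.4723665527
0.01426423391	0.01831563889	0.02351774586	0.03019738342	0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831	0.6065306597
0.01110899654	0.01426423391	0.01831563889	0.02351774586	0.03019738342	0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1	0.7788007831
0.008651695203	0.01110899654	0.01426423391	0.01831563889	0.02351774586	0.03019738342	0.03877420783	0.04978706837	0.06392786121	0.08208499862	0.1053992246	0.1353352832	0.1737739435	0.2231301601	0.2865047969	0.3678794412	0.4723665527	0.6065306597	0.7788007831	1
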