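0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487	0.0002263981519	0.0001373174204	8.32872256e-05	5.051625589e-05	3.063965801e-05	1.858389199e-05
0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487	0.0002263981519	0.0001373174204	8.32872256e-05	5.051625589e-05	3.063965801e-05
0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487	0.0002263981519	0.0001373174204	8.32872256e-05	5.051625589e-05
0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487	0.0002263981519	0.0001373174204	8.32872256e-05
0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487	0.0002263981519	0.0001373174204
0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487	0.0002263981519
0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823	0.0003732674487
0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123	0.0006154139823
0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645	0.001014646123
0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118	0.001672868645
0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439	0.002758094118
0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122	0.004547328439
0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026	0.007497277122
0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216	0.01236092026
0.0002263981519	0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494	0.02037971216
0.0001373174204	0.0002263981519	0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124	0.03360046494
8.32872256e-05	0.0001373174204	0.0002263981519	0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326	0.05539780124
5.051625589e-05	8.32872256e-05	0.0001373174204	0.0002263981519	0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365	0.09133553326
3.063965801e-05	5.051625589e-05	8.32872256e-05	0.0001373174204	0.0002263981519	0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204	0.1505868365
1.858389199e-05	3.063965801e-05	5.051625589e-05	8.32872256e-05	0.0001373174204	0.0002263981519	0.0003732674487	0.0006154139823	0.001014646123	0.001672868645	0.002758094118	0.004547328439	0.007497277122	0.01236092026	0.02037971216	0.03360046494	0.05539780124	0.09133553326	0.1505868365	0.2482757204
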