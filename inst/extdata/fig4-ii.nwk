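(Andean[&Ne=10000]:1250,(West[&Ne=10000]:833.333333333,(North[&Ne=10000]:416.666666667,South[&Ne=10000]:416.666666667)[&Ne=10000]:416.666666667)[&Ne=10000]:416.666666667)[&Ne=10000];
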