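(West[&Ne=10000]:1250,Andean[&Ne=10000]:1250,North[&Ne=10000]:1250,South[&Ne=10000]:1250)[&Ne=10000];
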