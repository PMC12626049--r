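leaflet_id,word_count,fkg,fre,ari,gfi,discern,pemat_u,pemat_a,misinfo_total,references
Stroke Association,1185,8.3,60,8.63,9.7,65,76.9,40,0,2
ChatGPT-5 (Thinking),532,7.94,63,9.06,10.3,58,76.9,60,1,1
ChatGPT-5o (Standard),1346,9.71,48,10.78,11.4,64,84.6,60,0,0
Microsoft Copilot,380,6.39,45,6.93,7.8,39,92,60,2,1
DeepSeek v3.1,790,7.5,68,8.48,9.2,48,84.6,60,2,1
Gemini 2.5 Flash,946,8.64,56,9.09,10.3,55,76.9,40,1,1
Claude Sonnet 4,850,9,44,9.83,11.9,59,92,60,2,0
Perplexity AI (free),453,10.53,48,11.82,11.8,38,76.9,40,3,1
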