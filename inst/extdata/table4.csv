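leaflet_id,inappropriate_content,missing_content,potential_harm,total
Stroke Association,0,0,0,0
ChatGPT-5 (Thinking),0,1,0,1
ChatGPT-5o (Standard),0,0,0,0
Microsoft Copilot,0,2,0,2
DeepSeek v3.1,1,1,0,2
Gemini 2.5 Flash,0,1,0,1
Claude Sonnet 4,1,1,0,2
Perplexity AI (free),0,2,1,3
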