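Thank you for seeing
Thank you for reviewing
I would be grateful if you could see
Please could you see
Re
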