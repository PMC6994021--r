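token,role
not,negator
never,negator
no,negator
didn't,negator
didnt,negator
don't,negator
dont,negator
won't,negator
wont,negator
can't,negator
cant,negator
cannot,negator
wasn't,negator
wasnt,negator
couldn't,negator
couldnt,negator
declined,negator
refused,negator
refusing,negator
denied,negator
without,negator
avoided,negator
stopped,negator
against,negator
but,terminator
however,terminator
although,terminator
though,terminator
except,terminator
yet,terminator
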